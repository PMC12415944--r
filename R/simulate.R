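# Multispecies-coalescent synthetic data generator.
#
# Time is measured in expected substitutions per site throughout, so tree
# heights translate directly into sequence divergences without a separate
# calibration constant. `theta` is the within-species coalescent scale
# parameterised as the expected pairwise within-species divergence: j
# lineages coalesce at rate j(j-1)/theta, so a pair coalesces after an
# expected theta/2 and sits at expected divergence theta.

#' Simulation configuration
#'
#' The defaults describe the study conditions the package's experiments
#' emulate: 38 samples in 7 species (two species with only two samples), a
#' chloroplast-genome-scale alignment of 100 genes x 1000 nt, mean
#' within-species divergence ~0.2% (maxima under ~1%) and between-species
#' divergences of roughly 3.5-8%, i.e. a clean barcode gap of at least
#' twice the deepest within-species divergence. The species (Yule) tree
#' is conditioned on its youngest split being at least `min_split` old
#' (rejection sampling) so that delimited species are genuinely separated
#' lineages; an unconditioned Yule tree routinely places sister species
#' within coalescent distance of each other, which contradicts both the
#' barcode-gap premise and the divergence summaries the conditions are
#' taken from.
#'
#' @param n_species positive integer.
#' @param samples_per_species positive integer vector, one entry per
#'   species (recycled if length 1).
#' @param birth_rate Yule splitting rate; only the tree shape matters
#'   because the root age is rescaled to `root_height`.
#' @param root_height species-tree root age, expected substitutions/site.
#' @param theta within-species coalescent scale (expected pairwise
#'   within-species divergence), same units.
#' @param n_genes number of genes.
#' @param gene_lengths integer vector of gene lengths in nt (recycled).
#' @param rate_multipliers per-gene positive rate multipliers, or `NULL`
#'   to draw them log-normally (`sdlog = rate_sigma`, unit mean).
#' @param rate_sigma log-normal sigma used when `rate_multipliers` is
#'   `NULL`; among-gene rate spread.
#' @param min_split minimum allowed age of the youngest species split.
#' @param shared_genealogy if `TRUE` (default) all genes share a single
#'   gene genealogy, as expected for a non-recombining uniparentally
#'   inherited chromosome; `FALSE` draws i.i.d. genealogies per gene for
#'   power experiments.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_species = 7L,
                       samples_per_species = c(8L, 2L, 2L, 9L, 7L, 6L, 4L),
                       birth_rate = 1,
                       root_height = 0.04,
                       theta = 0.002,
                       n_genes = 100L,
                       gene_lengths = 1000L,
                       rate_multipliers = NULL,
                       rate_sigma = 0.5,
                       min_split = 0.016,
                       shared_genealogy = TRUE,
                       seed = 1L) {
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 1L)
  samples_per_species <- as.integer(rep(samples_per_species,
                                        length.out = n_species))
  if (any(samples_per_species < 1L)) stopf("samples_per_species must be >= 1")
  if (root_height < 0 || theta < 0 || birth_rate < 0 || rate_sigma < 0 ||
      min_split < 0)
    stopf("rates, heights, theta and sigma must be >= 0")
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 1L)
  gene_lengths <- as.integer(rep(gene_lengths, length.out = n_genes))
  if (any(gene_lengths < 1L)) stopf("gene lengths must be >= 1")
  if (!is.null(rate_multipliers)) {
    if (length(rate_multipliers) != n_genes)
      stopf("rate_multipliers must have length n_genes")
    if (any(rate_multipliers < 0)) stopf("rate multipliers must be >= 0")
  }
  if (n_species >= 2L && root_height <= theta)
    warnf("root_height <= theta: species will not be separated")
  structure(list(n_species = n_species,
                 samples_per_species = samples_per_species,
                 birth_rate = birth_rate, root_height = root_height,
                 theta = theta, n_genes = n_genes,
                 gene_lengths = gene_lengths,
                 rate_multipliers = rate_multipliers,
                 rate_sigma = rate_sigma, min_split = min_split,
                 shared_genealogy = shared_genealogy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d species / %d samples, %d genes ",
                     "(total %d nt), root %.4g, theta %.4g, seed %d\n"),
              x$n_species, sum(x$samples_per_species), x$n_genes,
              sum(x$gene_lengths), x$root_height, x$theta, x$seed))
  invisible(x)
}

#' Simulate a Yule species tree
#'
#' A pure-birth tree conditioned on `n_species` tips, with the root age
#' rescaled to exactly `root_height` and, optionally, rejection-sampled
#' until its youngest internal node is at least `min_split` old. Tips are
#' labelled `sp1..spN`.
#'
#' @param n_species number of species (>= 1; a single species gives a
#'   single-tip tree of height 0).
#' @param birth_rate Yule splitting rate (> 0 when `n_species >= 2`).
#' @param root_height target root age.
#' @param min_split minimum age of the youngest split (0 disables the
#'   conditioning).
#' @param seed integer seed or `NULL` to use the ambient RNG stream.
#' @param max_tries rejection-sampling cap.
#' @return an ultrametric `phylo`.
#' @export
yule_species_tree <- function(n_species, birth_rate = 1, root_height = 0.04,
                              min_split = 0, seed = NULL, max_tries = 10000L) {
  n_species <- as.integer(n_species)
  if (n_species < 1L) stopf("n_species must be >= 1")
  if (n_species == 1L) {
    tr <- ape::read.tree(text = "(sp1:0);")
    return(tr)
  }
  if (birth_rate <= 0) stopf("birth_rate must be > 0 for n_species >= 2")
  if (min_split >= root_height) stopf("min_split must be < root_height")
  with_seed_opt(seed, {
    for (k in seq_len(max_tries)) {
      tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
      bt <- ape::branching.times(tr)
      tr$edge.length <- tr$edge.length * root_height / max(bt)
      if (n_species == 2L || min(bt) * root_height / max(bt) >= min_split) {
        tr$tip.label <- paste0("sp", seq_len(n_species))
        return(tr)
      }
    }
    stopf("no Yule tree satisfied min_split = %g in %d tries", min_split,
          max_tries)
  })
}

#' Simulate a gene genealogy under the multispecies coalescent
#'
#' Within each species-tree branch, the lineages present coalesce at rate
#' `j(j-1)/theta` for `j` lineages; survivors are handed to the parent
#' branch, and remaining lineages coalesce freely above the root. Every
#' coalescence is therefore at least as old as the species node below it.
#' With `theta = 0`, lineages of a species coalesce immediately at the
#' species-tip age (a documented limit, not an error).
#'
#' @param species_tree ultrametric `phylo` with species tip labels.
#' @param samples_per_species integer vector, either named by species tip
#'   label or given in `species_tree$tip.label` order.
#' @param theta coalescent scale (expected pairwise divergence), >= 0.
#' @param seed integer seed or `NULL`.
#' @return an ultrametric `phylo` over samples named `<species>_<k>`.
#' @export
msc_genealogy <- function(species_tree, samples_per_species, theta,
                          seed = NULL) {
  if (theta < 0) stopf("theta must be >= 0")
  sp <- species_tree$tip.label
  nsp <- length(sp)
  if (is.null(names(samples_per_species))) {
    if (length(samples_per_species) != nsp)
      stopf("samples_per_species must align with species-tree tips")
    names(samples_per_species) <- sp
  }
  if (!all(sp %in% names(samples_per_species)))
    stopf("samples_per_species missing species: %s",
          paste(setdiff(sp, names(samples_per_species)), collapse = ", "))

  with_seed_opt(seed, {
    if (nsp == 1L) {
      lin <- init_lineages(sp, samples_per_species[[sp]])
      lin <- coalesce_segment(lin, 0, Inf, theta)
      return(lineage_to_phylo(lin))
    }
    ages <- c(stats::setNames(rep(0, nsp), seq_len(nsp)),
              ape::branching.times(species_tree))
    nnode <- nsp + species_tree$Nnode
    parent <- integer(nnode)
    parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
    root <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
    # lineage sets waiting at each node, filled tips-first by age order
    pool <- vector("list", nnode)
    for (i in seq_len(nsp))
      pool[[i]] <- init_lineages(sp[i], samples_per_species[[sp[i]]])
    ord <- order(ages[as.character(seq_len(nnode))])
    age_of <- function(v) unname(ages[as.character(v)])
    for (v in ord) {
      lin <- pool[[v]]
      if (v == root) {
        lin <- coalesce_segment(lin, age_of(v), Inf, theta)
        return(lineage_to_phylo(lin))
      }
      lin <- coalesce_segment(lin, age_of(v), age_of(parent[v]), theta)
      pool[[parent[v]]] <- c(pool[[parent[v]]], lin)
    }
  })
}

init_lineages <- function(species, n) {
  lapply(seq_len(n), function(k)
    list(txt = sprintf("%s_%d", species, k), age = 0))
}

# run the coalescent over one species-tree branch [t0, t1)
coalesce_segment <- function(lineages, t0, t1, theta) {
  t <- t0
  while (length(lineages) >= 2L) {
    j <- length(lineages)
    if (theta <= 0) {
      wait <- 0
    } else {
      wait <- stats::rexp(1L, rate = j * (j - 1) / theta)
    }
    if (t + wait > t1) break
    t <- t + wait
    pick <- sample.int(j, 2L)
    a <- lineages[[pick[1]]]; b <- lineages[[pick[2]]]
    merged <- list(txt = sprintf("(%s:%.12g,%s:%.12g)", a$txt, t - a$age,
                                 b$txt, t - b$age),
                   age = t)
    lineages <- c(lineages[-pick], list(merged))
  }
  lineages
}

lineage_to_phylo <- function(lineages) {
  stopifnot(length(lineages) == 1L)
  ape::read.tree(text = paste0(lineages[[1]]$txt, ";"))
}

#' Evolve sequences along a gene tree under Jukes-Cantor
#'
#' The root sequence is uniform over A/C/G/T; each site evolves
#' independently along every branch with the JC transition probabilities,
#' so two tips separated by path length `d` differ at an expected fraction
#' `(3/4)(1 - exp(-4 d / 3))` of sites.
#'
#' @param gene_tree `phylo` with branch lengths in expected subs/site.
#' @param n_sites number of sites (>= 1).
#' @param rate_multiplier non-negative scalar scaling all branch lengths;
#'   0 yields identical sequences.
#' @param seed integer seed or `NULL`.
#' @param name gene name recorded in the partition table.
#' @return a single-gene [alignment()].
#' @export
evolve_jc <- function(gene_tree, n_sites, rate_multiplier = 1, seed = NULL,
                      name = "gene1") {
  if (n_sites < 1) stopf("n_sites must be >= 1")
  if (rate_multiplier < 0) stopf("rate_multiplier must be >= 0")
  with_seed_opt(seed, {
    dat <- phangorn::simSeq(gene_tree, l = as.integer(n_sites),
                            rate = rate_multiplier)
    m <- toupper(as.character(dat))
    alignment(m[gene_tree$tip.label, , drop = FALSE], name = name)
  })
}

#' Generate a full synthetic dataset
#'
#' Draws one species tree, gene genealogies (one shared genealogy by
#' default), per-gene rate multipliers if not supplied, evolves each gene
#' under Jukes-Cantor and concatenates the genes in declared order.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (concatenated, with gene partitions),
#'   `genes` (per-gene alignments), `truth` (named character vector sample
#'   -> true species), `species_tree`, `gene_trees`, `rate_multipliers`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_opt(config$seed, {
    sp_tree <- yule_species_tree(config$n_species, config$birth_rate,
                                 config$root_height,
                                 min_split = config$min_split)
    spp <- stats::setNames(config$samples_per_species, sp_tree$tip.label)
    gene_trees <- if (config$shared_genealogy) {
      rep(list(msc_genealogy(sp_tree, spp, config$theta)), config$n_genes)
    } else {
      replicate(config$n_genes, msc_genealogy(sp_tree, spp, config$theta),
                simplify = FALSE)
    }
    mult <- config$rate_multipliers
    if (is.null(mult))
      mult <- stats::rlnorm(config$n_genes,
                            meanlog = -config$rate_sigma^2 / 2,
                            sdlog = config$rate_sigma)
    gene_names <- sprintf("g%03d", seq_len(config$n_genes))
    genes <- lapply(seq_len(config$n_genes), function(i)
      evolve_jc(gene_trees[[i]], config$gene_lengths[i], mult[i],
                name = gene_names[i]))
    names(genes) <- gene_names
    aln <- concat_alignments(genes)
    ids <- sample_ids(aln)
    truth <- stats::setNames(sub("_[0-9]+$", "", ids), ids)
    list(alignment = aln, genes = genes, truth = truth,
         species_tree = sp_tree, gene_trees = gene_trees,
         rate_multipliers = mult)
  })
}

#' Write the true species assignment as a two-column TSV
#' @param truth named character vector (sample -> species).
#' @param path output file.
#' @export
write_assignment <- function(truth, path) {
  utils::write.table(data.frame(sample = names(truth), species = truth),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
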