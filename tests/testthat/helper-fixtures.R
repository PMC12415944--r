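# Shared fixtures, built in code.

# alignment from a character vector of equal-length strings
aln_from_strings <- function(x, ids = NULL, name = "gene1") {
  if (is.null(ids)) ids <- paste0("s", seq_along(x))
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- ids
  alignment(m, name = name)
}

# small, fast simulation config (5 species, 15 samples, ~5 kb)
toy_config <- function(seed = 1, ...) {
  sim_config(n_species = 5, samples_per_species = c(3, 3, 3, 3, 3),
             n_genes = 10, gene_lengths = 500, seed = seed, ...)
}

# ultrametric 5-tip tree with two clusters ({a,b}, {c,d}) and singleton e
tree5 <- function() {
  read_newick("((a:0.1,b:0.1):0.9,((c:0.05,d:0.05):0.15,e:0.2):0.8);")
}

# two partitions describe the same clustering (labels ignored)
same_partition <- function(a, b) {
  setequal(lapply(split(names(a), a), sort),
           lapply(split(names(b), b), sort))
}

# ultrametric caterpillar of k species (n tips each): crowns at age
# `crown`, species joins at ages `stem`, 2*stem, ...; used for
# delimitation recovery fixtures with a stem/crown ratio of stem/crown
species_tree_fixture <- function(k = 5, crown = 0.002, stem = 0.1) {
  species_sub <- function(i) {  # 3 tips, internal nodes below crown_i
    ci <- crown * (0.75 + 0.05 * i)   # distinct ages across species
    sprintf("((s%d_1:%.10g,s%d_2:%.10g):%.10g,s%d_3:%.10g)",
            i, ci / 2, i, ci / 2, ci / 2, i, ci)
  }
  crown_of <- function(i) crown * (0.75 + 0.05 * i)
  cur <- species_sub(1)
  cur_h <- crown_of(1)
  for (i in 2:k) {
    d <- stem * (i - 1)
    cur <- sprintf("(%s:%.10g,%s:%.10g)", cur, d - cur_h, species_sub(i),
                   d - crown_of(i))
    cur_h <- d
  }
  read_newick(paste0(cur, ";"))
}
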