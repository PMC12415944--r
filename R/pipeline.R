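# Experiment orchestration: the per-dataset method suite, the
# gene-order-randomised size-ladder scaling experiment, gene-by-gene
# delimitation and the Poisson regression of species counts on gene
# informativeness.

#' Run the three delimitation methods on one alignment
#'
#' ASAP-style ranking runs on the p-distance matrix, PTP on the
#' neighbour-joining tree rooted on its longest branch, GMYC on the UPGMA
#' tree. With `dedup = TRUE` duplicate haplotypes are collapsed first; the
#' species count is computed on the unique haplotypes and memberships are
#' mapped back to all samples afterwards. Degenerate inputs (fewer than 3
#' unique sequences, or an invariant alignment) short-circuit to a single
#' species with a warning.
#'
#' @param aln a [alignment()] object with >= 4 samples.
#' @param methods subset of `c("asap", "ptp", "gmyc")`.
#' @param dedup collapse duplicate haplotypes before analysis?
#' @param seed integer seed (ASAP permutations, GMYC multi-starts).
#' @param n_perm permutations for the ASAP-style panmixia tests.
#' @return a list with one entry per method (each `list(partition,
#'   n_species, fit)`), plus `n_unique`, `dedup` and `degenerate`.
#' @export
run_method_suite <- function(aln, methods = c("asap", "ptp", "gmyc"),
                             dedup = FALSE, seed = 1, n_perm = 999) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_samples(aln) < 4L) stopf("need at least 4 samples")
  map <- NULL
  work <- aln
  if (dedup) {
    dd <- dedup_haplotypes(aln)
    work <- dd$alignment
    map <- dd$map
  }
  n_u <- n_samples(work)
  expand <- function(part) {
    if (is.null(map)) return(part[sample_ids(aln)])
    full <- part
    for (rep_id in names(map))
      for (dup in map[[rep_id]]) full[dup] <- part[rep_id]
    full[sample_ids(aln)]
  }
  out <- list(n_unique = n_u, dedup = dedup, degenerate = FALSE)
  pd <- if (n_u >= 2L) p_distance_matrix(work) else NULL
  if (n_u < 3L || max(pd$d) == 0) {
    warnf("degenerate alignment (%d unique haplotypes, max distance %g): one species reported",
          n_u, if (is.null(pd)) 0 else max(pd$d))
    part <- stats::setNames(rep("sp01", n_u), sample_ids(work))
    for (mth in methods)
      out[[mth]] <- list(partition = expand(part), n_species = 1L,
                         fit = NULL)
    out$degenerate <- TRUE
    return(out)
  }
  if ("asap" %in% methods) {
    fit <- run_asap(pd, n_perm = n_perm, seed = seed)
    out$asap <- list(partition = expand(fit$best_partition),
                     n_species = length(unique(fit$best_partition)),
                     fit = fit)
  }
  if ("ptp" %in% methods) {
    tr <- root_on_longest_branch(nj_tree(pd))
    fit <- fit_ptp(tr, mode = "greedy")
    out$ptp <- list(partition = expand(fit$partition),
                    n_species = fit$n_species, fit = fit)
  }
  if ("gmyc" %in% methods) {
    tr <- upgma_tree(pd)
    fit <- suppressWarnings(fit_gmyc(tr, seed = seed))
    out$gmyc <- list(partition = expand(fit$partition),
                     n_species = fit$n_entities, fit = fit)
  }
  out
}

#' Size-ladder scaling experiment
#'
#' For each of `R` replicates, the genes are concatenated in a seeded
#' random order and subset into nested prefixes at the ladder lengths;
#' each sub-alignment is analysed with the method suite, optionally before
#' and after haplotype deduplication. The GMYC coalescent lambda is
#' recorded per run, which is the diagnostic that balloons with alignment
#' length.
#'
#' @param genes list of per-gene [alignment()] objects sharing samples.
#' @param R number of gene-order replicates.
#' @param ladder integer vector of target lengths (default
#'   [size_ladder()]); a rung larger than the total length uses the full
#'   alignment (flagged in the `clipped` column).
#' @param dedup `"both"` (default), `"with"` or `"without"`.
#' @param seed integer master seed.
#' @param n_perm ASAP permutation count.
#' @param methods methods to run.
#' @return data.frame of records: replicate, L, dedup, method, n_species,
#'   lambda_coal (GMYC, else NA), n_unique, clipped, runtime_s.
#' @export
run_scaling_experiment <- function(genes, R = 10, ladder = size_ladder(),
                                   dedup = c("both", "with", "without"),
                                   seed = 1, n_perm = 999,
                                   methods = c("asap", "ptp", "gmyc")) {
  dedup <- match.arg(dedup)
  dd_flags <- switch(dedup, both = c(FALSE, TRUE), with = TRUE,
                     without = FALSE)
  rows <- list()
  for (r in seq_len(R)) {
    full <- concat_alignments(genes, order = "random", seed = seed + 7919L * r)
    for (li in seq_along(ladder)) {
      L <- ladder[li]
      clipped <- L > aln_width(full)
      if (clipped)
        warnf("rung %d exceeds total length %d: full alignment used", L,
              aln_width(full))
      sub <- subset_prefix(full, min(L, aln_width(full)))
      for (dd in dd_flags) {
        run_seed <- (seed + 104729L * r + 373L * li + as.integer(dd)) %%
          .Machine$integer.max
        t0 <- proc.time()[["elapsed"]]
        suite <- suppressWarnings(
          run_method_suite(sub, methods = methods, dedup = dd,
                           seed = run_seed, n_perm = n_perm))
        dt <- proc.time()[["elapsed"]] - t0
        for (mth in methods) {
          lam <- if (mth == "gmyc" && !is.null(suite$gmyc$fit))
            suite$gmyc$fit$lambda_coal else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, L = L, dedup = dd, method = mth,
            n_species = suite[[mth]]$n_species,
            lambda_coal = lam, n_unique = suite$n_unique,
            clipped = clipped, runtime_s = dt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate scaling records into mean +/- SE cells
#'
#' @param records output of [run_scaling_experiment()].
#' @return data.frame with one row per (L, method, dedup): replicate
#'   count, mean and standard error (sd / sqrt(R)) of the species count,
#'   and of the GMYC coalescent lambda where present.
#' @export
aggregate_scaling <- function(records) {
  key <- interaction(records$L, records$method, records$dedup, drop = TRUE)
  cells <- split(records, key)
  se <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  out <- lapply(cells, function(cc) {
    lam <- cc$lambda_coal[is.finite(cc$lambda_coal)]
    data.frame(L = cc$L[1], method = cc$method[1], dedup = cc$dedup[1],
               n_rep = nrow(cc),
               mean_species = mean(cc$n_species), se_species = se(cc$n_species),
               mean_lambda = if (length(lam)) mean(lam) else NA_real_,
               se_lambda = se(cc$lambda_coal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, out$dedup, out$L), ]
}

#' Gene-by-gene delimitation comparison
#'
#' Filters genes by aligned length, runs the method suite on each gene
#' (after haplotype deduplication, as in the study protocol) and collects
#' per-gene informativeness covariates: length, parsimony-informative
#' sites and the relative rate against the concatenated reference.
#'
#' @param genes named list of per-gene [alignment()] objects.
#' @param min_len genes must be strictly longer than this (default 450
#'   nt).
#' @param dedup collapse duplicate haplotypes per gene (default `TRUE`).
#' @param seed,n_perm passed to [run_method_suite()].
#' @param methods methods to run.
#' @return list with `records` (data.frame: gene, length, pis, rate, one
#'   n_species column per method, degenerate flag) and `summary`
#'   (data.frame: method, mu, sigma of the species-count distribution).
#' @export
gene_by_gene <- function(genes, min_len = 450, dedup = TRUE, seed = 1,
                         n_perm = 999, methods = c("asap", "ptp", "gmyc")) {
  keep <- vapply(genes, aln_width, integer(1)) > min_len
  genes_k <- genes[keep]
  if (length(genes_k) == 0L) stopf("no gene longer than %d nt", min_len)
  ref <- mean_pairwise(p_distance_matrix(concat_alignments(genes)))
  rows <- lapply(names(genes_k), function(nm) {
    g <- genes_k[[nm]]
    suite <- suppressWarnings(
      run_method_suite(g, methods = methods, dedup = dedup,
                       seed = seed, n_perm = n_perm))
    cs <- count_sites(g)
    row <- data.frame(gene = nm, length = aln_width(g), pis = cs[["pis"]],
                      rate = gene_relative_rate(g, ref),
                      degenerate = suite$degenerate,
                      stringsAsFactors = FALSE)
    for (mth in methods) row[[paste0(mth, "_species")]] <-
        suite[[mth]]$n_species
    row
  })
  records <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(methods, function(mth) {
    v <- records[[paste0(mth, "_species")]]
    data.frame(method = mth, mu = mean(v), sigma = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  list(records = records, summary = summary)
}

#' Poisson regression of species counts on gene features
#'
#' Fits, per method, a log-link Poisson GLM of the inferred species count
#' on `log10(PIS)` and the relative gene rate (the informativeness
#' covariates of the gene-by-gene comparison). Zero-variance predictors
#' are dropped with a warning; non-convergence is an error.
#'
#' @param records the `records` data.frame from [gene_by_gene()] (or any
#'   data.frame with `pis`, `rate` and `<method>_species` columns).
#' @param methods methods whose count columns to model.
#' @return named list of data.frames (term, estimate, se, z, p_value).
#' @export
poisson_regression_species <- function(records,
                                       methods = c("asap", "ptp", "gmyc")) {
  if (nrow(records) < 10L) stopf("need at least 10 gene records")
  out <- list()
  for (mth in methods) {
    col <- paste0(mth, "_species")
    if (!col %in% names(records)) next
    df <- data.frame(count = records[[col]], log10_pis = log10(records$pis),
                     rate = records$rate)
    preds <- c("log10_pis", "rate")
    for (p in preds) if (stats::var(df[[p]]) == 0) {
      warnf("predictor '%s' has zero variance: dropped for %s", p, mth)
      preds <- setdiff(preds, p)
    }
    fml <- stats::reformulate(if (length(preds)) preds else "1", "count")
    fit <- stats::glm(fml, family = stats::poisson(), data = df)
    if (!fit$converged) stopf("Poisson GLM did not converge for %s", mth)
    cf <- summary(fit)$coefficients
    out[[mth]] <- data.frame(term = rownames(cf), estimate = cf[, 1],
                             se = cf[, 2], z = cf[, 3], p_value = cf[, 4],
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Plot mean species counts along the scaling ladder
#'
#' Base-graphics view of [aggregate_scaling()] output: mean +/- SE of the
#' species count against log10 alignment length, one line per method.
#'
#' @param agg output of [aggregate_scaling()].
#' @param dedup which dedup stratum to show.
#' @export
plot_scaling <- function(agg, dedup = TRUE) {
  sub <- agg[agg$dedup == dedup, ]
  if (nrow(sub) == 0L) stopf("no records for dedup = %s", dedup)
  xs <- log10(sub$L)
  cols <- stats::setNames(c("#1b9e77", "#d95f02", "#7570b3"),
                          c("asap", "ptp", "gmyc"))
  plot(range(xs), range(sub$mean_species + sub$se_species,
                        sub$mean_species - sub$se_species, na.rm = TRUE),
       type = "n", xlab = "log10 alignment length (nt)",
       ylab = "inferred species (mean +/- SE)")
  for (mth in unique(sub$method)) {
    ss <- sub[sub$method == mth, ]
    ss <- ss[order(ss$L), ]
    graphics::lines(log10(ss$L), ss$mean_species, col = cols[[mth]], lwd = 2)
    graphics::points(log10(ss$L), ss$mean_species, col = cols[[mth]], pch = 16)
    graphics::arrows(log10(ss$L), ss$mean_species - ss$se_species,
                     log10(ss$L), ss$mean_species + ss$se_species,
                     angle = 90, code = 3, length = 0.03, col = cols[[mth]])
  }
  graphics::legend("bottomright", legend = unique(sub$method),
                   col = cols[unique(sub$method)], lwd = 2, bty = "n")
  invisible(sub)
}
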