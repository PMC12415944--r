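# Maximum-likelihood Poisson tree processes (PTP).
#
# A partition of the tips into species is encoded by its set S of
# "speciation" internal nodes, which must be ancestor-closed (if a node is
# in S so are all its ancestors). Species crowns are the nodes or tips
# whose parent is in S but which are not themselves in S; with S empty the
# whole tree is one species. Edges whose parent node is in S belong to the
# between-species (speciation) class B, all other edges to the
# within-species (coalescent) class W — in particular the two edges
# descending from the root are class B unless the root lies inside a
# single all-encompassing species. Branch lengths in each class are
# modelled as i.i.d. exponential; at the MLE rate lambda = n / sum(b) a
# class contributes n log(lambda) - n to the log-likelihood, an empty
# class contributes 0, and a non-empty class with zero total length yields
# -Inf (the degenerate situation created by duplicate haplotypes).

ptp_support <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  list(n = n, parent = parent, root = root, children = children,
       edge_parent = tree$edge[, 1], bl = tree$edge.length)
}

loglik_from_S <- function(sup, S) {
  inB <- sup$edge_parent %in% S
  class_ll <- function(b) {
    k <- length(b)
    if (k == 0L) return(0)
    tot <- sum(b)
    if (tot <= 0) return(-Inf)
    k * log(k / tot) - k
  }
  lB <- sup$bl[inB]; lW <- sup$bl[!inB]
  list(logL = class_ll(lB) + class_ll(lW),
       lambda_B = if (length(lB)) length(lB) / sum(lB) else NA_real_,
       lambda_W = if (length(lW)) length(lW) / sum(lW) else NA_real_)
}

partition_from_S <- function(tree, sup, S) {
  crowns <- if (length(S) == 0L) sup$root else {
    cand <- setdiff(c(seq_len(sup$n), unique(sup$edge_parent)), S)
    cand[sup$parent[cand] %in% S]
  }
  part <- character(0)
  for (k in seq_along(crowns))
    part[clade_tips(tree, crowns[k])] <- sprintf("sp%02d", k)
  part[tree$tip.label]
}

S_from_partition <- function(tree, sup, partition) {
  missing <- setdiff(tree$tip.label, names(partition))
  if (length(missing))
    stopf("partition misses tips: %s", paste(missing, collapse = ", "))
  lab <- partition[tree$tip.label]
  internal <- unique(sup$edge_parent)
  inside <- integer(0)
  for (sp in unique(lab)) {
    tips <- tree$tip.label[lab == sp]
    if (length(tips) < 2L) next
    crown <- ape::getMRCA(tree, tips)
    below <- clade_tips(tree, crown)
    if (!setequal(below, tips))
      stopf("species '%s' is not convex on the tree (crown subtends %d tips, species has %d)",
            sp, length(below), length(tips))
    desc <- phangorn::Descendants(tree, crown, type = "all")
    inside <- c(inside, crown, desc[desc > sup$n])
  }
  setdiff(internal, inside)
}

#' PTP two-class log-likelihood of a species partition
#'
#' Each multi-member species must span a complete subtree (be convex);
#' otherwise an error is raised.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param partition named character vector tip -> species label.
#' @return list with `logL`, `lambda_B` (speciation class) and `lambda_W`
#'   (within-species class); an empty class has `NA` rate.
#' @export
ptp_loglik <- function(tree, partition) {
  sup <- ptp_support(tree)
  S <- S_from_partition(tree, sup, partition)
  loglik_from_S(sup, S)
}

#' Fit the maximum-likelihood PTP model
#'
#' `mode = "greedy"` starts from a single species and repeatedly splits a
#' multi-member species at its crown into its two child subtrees, always
#' taking the best-scoring move. Because trees built from well-separated
#' species often have short backbone edges near the root, a strict
#' hill-climb stalls on plateaus where every single split transiently
#' mixes edge classes; the search therefore walks the full best-move path
#' down to all-singletons, then refines the best state visited (and,
#' independently, the all-singleton state) by single split/merge moves to
#' a local optimum of both move types — a superset of the plain
#' hill-climb, still bounded above by the exhaustive optimum.
#' `mode = "exhaustive"` (trees of up to 12 tips) enumerates
#' every convex partition (ancestor-closed speciation-node sets) and
#' returns the global maximum, which upper-bounds the greedy solution and
#' serves as its oracle in tests. The single-rate null model is the
#' one-species partition; `LR = 2 (logL - logL_null)` is referred to
#' chi-squared with 1 df.
#'
#' @param tree rooted `phylo` with branch lengths and >= 3 tips (root an
#'   unrooted tree with [root_on_longest_branch()] first).
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param alpha significance level reported alongside the test; the ML
#'   partition itself is never altered by it.
#' @return an object of class `ptp_fit`.
#' @export
fit_ptp <- function(tree, mode = c("greedy", "exhaustive"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (ape::Ntip(tree) < 3L) stopf("need at least 3 tips")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  sup <- ptp_support(tree)
  null_ll <- loglik_from_S(sup, integer(0))$logL
  trace <- integer(0)

  if (mode == "greedy") {
    S <- integer(0)
    crowns <- sup$root
    best_S <- S
    best_ll <- null_ll
    repeat {
      split_cands <- crowns[crowns > sup$n]  # internal crowns only
      if (length(split_cands) == 0L) break
      lls <- vapply(split_cands, function(v)
        loglik_from_S(sup, c(S, v))$logL, numeric(1))
      best <- which.max(lls)
      v <- split_cands[best]
      S <- c(S, v)
      crowns <- c(setdiff(crowns, v), sup$children[[as.character(v)]])
      trace <- c(trace, v)
      if (lls[best] > best_ll + 1e-12) {
        best_ll <- lls[best]
        best_S <- S
      }
    }
    # refine by single split/merge moves until a local optimum of both
    # move types, starting from the best path state and (independently)
    # from the all-singleton state; keep the better local optimum
    internal <- unique(sup$edge_parent)
    hill_climb <- function(S) {
      ll <- loglik_from_S(sup, S)$logL
      for (iter in 1:200) {
        adds <- setdiff(internal[internal == sup$root |
                                   sup$parent[internal] %in% S], S)
        drops <- S[!S %in% sup$parent[S]]  # leaves of S: removal stays closed
        moves <- c(lapply(adds, function(v) c(S, v)),
                   lapply(drops, function(v) setdiff(S, v)))
        if (length(moves) == 0L) break
        lls <- vapply(moves, function(Sm) loglik_from_S(sup, Sm)$logL,
                      numeric(1))
        if (max(lls) <= ll + 1e-12) break
        S <- moves[[which.max(lls)]]
        ll <- max(lls)
      }
      list(S = S, logL = ll)
    }
    r1 <- hill_climb(best_S)
    r2 <- hill_climb(internal)
    S <- if (r1$logL >= r2$logL) r1$S else r2$S
  } else {
    if (ape::Ntip(tree) > 12L)
      stopf("exhaustive mode is limited to 12 tips")
    internal <- sort(unique(sup$edge_parent))
    S <- integer(0); cur <- -Inf
    for (mask in 0:(2^length(internal) - 1L)) {
      Sc <- internal[bitwAnd(bitwShiftL(1L, seq_along(internal) - 1L),
                             mask) != 0L]
      ok <- all(Sc == sup$root | sup$parent[Sc] %in% Sc)
      if (!ok) next
      ll <- loglik_from_S(sup, Sc)$logL
      if (ll > cur) { cur <- ll; S <- Sc }
    }
  }

  final <- loglik_from_S(sup, S)
  part <- partition_from_S(tree, sup, S)
  LR <- 2 * (final$logL - null_ll)
  structure(list(partition = part,
                 n_species = length(unique(part)),
                 lambda_B = final$lambda_B, lambda_W = final$lambda_W,
                 logL = final$logL, logL_null = null_ll,
                 LR = LR,
                 p_value = stats::pchisq(max(LR, 0), df = 1,
                                         lower.tail = FALSE),
                 alpha = alpha, mode = mode, trace = trace,
                 speciation_nodes = S),
            class = "ptp_fit")
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat(sprintf(paste0("PTP fit (%s): %d species\n",
                     "  logL %.4f (null %.4f), LR %.3f, p = %.4g\n",
                     "  lambda_B %.4g, lambda_W %.4g\n"),
              x$mode, x$n_species, x$logL, x$logL_null, x$LR, x$p_value,
              x$lambda_B, x$lambda_W))
  invisible(x)
}
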