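# Distance-based tree builders and rooting. These are deliberate
# desk-scale substitutes for likelihood/Bayesian tree inference: PTP runs
# on a neighbour-joining tree rooted on its longest branch, GMYC on an
# ultrametric UPGMA tree.

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on an uncorrected distance matrix. Taxa are
#' sorted lexicographically before clustering so the result is invariant
#' to input order; negative estimated branch lengths are clamped to 0.
#'
#' @param dist a `delim_dist`, `dist` or square matrix with >= 2 taxa.
#' @return an unrooted `phylo` (a 2-taxon input gives the trivial
#'   two-branch tree whose path length equals the input distance).
#' @export
nj_tree <- function(dist) {
  dist <- as_delim_dist(dist)
  n <- length(dist$ids)
  if (n < 2L) stopf("need at least 2 taxa")
  ord <- order(dist$ids)
  m <- dist$d[ord, ord, drop = FALSE]
  if (n == 2L) {
    txt <- sprintf("(%s:%.12g,%s:%.12g);", rownames(m)[1], m[1, 2] / 2,
                   rownames(m)[2], m[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA tree
#'
#' Average-linkage agglomeration; clusters merge at half the average
#' distance, so the result is rooted and ultrametric with node ages equal
#' to the merge heights / 2.
#'
#' @inheritParams nj_tree
#' @return a rooted ultrametric `phylo`.
#' @export
upgma_tree <- function(dist) {
  dist <- as_delim_dist(dist)
  n <- length(dist$ids)
  if (n < 2L) stopf("need at least 2 taxa")
  ord <- order(dist$ids)
  m <- dist$d[ord, ord, drop = FALSE]
  phangorn::upgma(stats::as.dist(m))
}

#' Re-root a tree on its longest branch
#'
#' The root is inserted at the midpoint of the single longest edge; ties
#' are broken towards the edge whose subtended leaf set is
#' lexicographically smallest. Total tree length is preserved.
#'
#' @param tree a `phylo`; a rooted input is unrooted first.
#' @return a rooted `phylo`.
#' @export
root_on_longest_branch <- function(tree) {
  if (ape::Ntip(tree) == 2L) {
    half <- sum(tree$edge.length) / 2
    txt <- sprintf("(%s:%.12g,%s:%.12g);", tree$tip.label[1], half,
                   tree$tip.label[2], half)
    return(ape::read.tree(text = txt))
  }
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  len <- tr$edge.length
  cand <- which(len == max(len))
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(e) {
      tips <- clade_tips(tr, tr$edge[e, 2])
      paste(sort(tips), collapse = "|")
    }, character(1))
    cand <- cand[order(keys)][1]
  }
  node <- tr$edge[cand, 2]
  rt <- phytools::reroot(tr, node.number = node,
                         position = tr$edge.length[cand] / 2)
  rt
}

clade_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

#' Read / write Newick trees
#'
#' Thin validating wrappers: parsing failures, unbalanced parentheses and
#' duplicate leaf labels raise errors; write/read round-trips are stable up
#' to float formatting.
#'
#' @param x Newick text or a file path (for [read_newick()]); a `phylo`
#'   (for [write_newick()]).
#' @param path optional output file for [write_newick()]; if `NULL` the
#'   Newick string is returned.
#' @return [read_newick()] returns a `phylo`; [write_newick()] a string or
#'   (invisibly) the path written.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x))
    tryCatch(ape::read.tree(x), error = function(e) NULL)
  else tryCatch(ape::read.tree(text = x), error = function(e) NULL)
  if (is.null(tr)) stopf("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate leaf label '%s'", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(x, path = NULL) {
  if (is.null(path)) return(ape::write.tree(x))
  ape::write.tree(x, file = path)
  invisible(path)
}

#' Node ages of an ultrametric tree
#'
#' Tip ages are forced to exactly zero; a tree failing the ultrametricity
#' check (relative tolerance 1e-6 of the root age) is an error.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @return named numeric vector of internal-node ages (names are node
#'   numbers), in `ape::branching.times()` order.
#' @keywords internal
node_ages <- function(tree) {
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  if (!ape::is.ultrametric(tree, tol = 1e-6, option = 2))
    stopf("tree is not ultrametric")
  bt <- ape::branching.times(tree)
  pmax(bt, 0)
}
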