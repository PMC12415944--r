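# Alignment informativeness statistics and uncorrected distances.
# Gaps ('-'), 'N', '?' and IUPAC ambiguity codes are treated as missing
# throughout (both for distances and site counts).

encode_states <- function(aln) {
  m <- matrix(match(aln$seq, DNA_STATES), nrow = nrow(aln$seq),
              dimnames = dimnames(aln$seq))
  m
}

#' Pairwise uncorrected p-distances with pairwise deletion
#'
#' For each pair of samples, sites where either sequence carries a gap,
#' `N`, `?` or an ambiguity code are excluded; the distance is the
#' mismatch proportion over the remaining (overlap) sites. An optional
#' Jukes-Cantor correction is available for sensitivity checks.
#'
#' @param aln a [alignment()] object with at least 2 rows.
#' @param min_overlap minimum number of jointly unambiguous sites required
#'   per pair; a pair below this is an error naming the pair.
#' @param model `"raw"` (uncorrected, default) or `"jc"`.
#' @return an object of class `delim_dist`: list with `d` (symmetric
#'   distance matrix, zero diagonal), `overlap` (site counts) and `ids`.
#' @export
p_distance_matrix <- function(aln, min_overlap = 1, model = c("raw", "jc")) {
  model <- match.arg(model)
  if (n_samples(aln) < 2L) stopf("need at least 2 sequences")
  enc <- encode_states(aln)
  n <- nrow(enc)
  ids <- rownames(enc)
  ok <- !is.na(enc)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ov <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ov) <- as.integer(rowSums(ok))
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]; oki <- ok[i, ]
    for (j in (i + 1L):n) {
      valid <- oki & ok[j, ]
      o <- sum(valid)
      if (o < min_overlap)
        stopf("pair (%s, %s) has overlap %d < min_overlap %d",
              ids[i], ids[j], o, min_overlap)
      p <- if (o > 0L) sum(xi[valid] != enc[j, valid]) / o else 0
      d[i, j] <- d[j, i] <- p
      ov[i, j] <- ov[j, i] <- o
    }
  }
  if (model == "jc") {
    if (any(d >= 0.75)) stopf("p-distance >= 0.75: JC correction undefined")
    d <- -0.75 * log(1 - 4 * d / 3)
  }
  structure(list(d = d, overlap = ov, ids = ids), class = "delim_dist")
}

#' @export
print.delim_dist <- function(x, ...) {
  cat(sprintf("p-distance matrix: %d samples, mean %.4g, max %.4g\n",
              length(x$ids), mean_pairwise(x), max(x$d)))
  invisible(x)
}

as_delim_dist <- function(x) {
  if (inherits(x, "delim_dist")) return(x)
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- colnames(x) <-
        paste0("s", seq_len(nrow(x)))
    return(structure(list(d = x, overlap = NULL, ids = rownames(x)),
                     class = "delim_dist"))
  }
  stopf("cannot interpret object of class '%s' as a distance matrix",
        paste(class(x), collapse = "/"))
}

mean_pairwise <- function(dist) {
  dist <- as_delim_dist(dist)
  mean(dist$d[upper.tri(dist$d)])
}

#' Write a distance matrix as square TSV or PHYLIP format
#' @param dist a `delim_dist` object.
#' @param path output file.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_distances <- function(dist, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  dist <- as_delim_dist(dist)
  if (format == "tsv") {
    utils::write.table(dist$d, path, sep = "\t", quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", length(dist$ids)), con)
    for (i in seq_along(dist$ids))
      writeLines(paste(c(sprintf("%-10s", dist$ids[i]),
                         sprintf("%.8f", dist$d[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable if it shows at least two distinct unambiguous
#' states, and parsimony-informative (PIS) if at least two states each
#' occur in at least two sequences. Because columns are scored
#' independently, PIS of a concatenation equals the sum over its genes.
#'
#' @param aln a [alignment()] object.
#' @return named integer vector `c(variable = ..., pis = ...)`.
#' @export
count_sites <- function(aln) {
  enc <- encode_states(aln)
  cnt <- vapply(seq_along(DNA_STATES),
                function(b) colSums(enc == b, na.rm = TRUE),
                numeric(ncol(enc)))
  if (ncol(enc) == 1L) cnt <- matrix(cnt, nrow = 1L)  # vapply drops dim
  n_states <- rowSums(cnt > 0L)
  c(variable = sum(n_states >= 2L),
    pis = sum(rowSums(cnt >= 2L) >= 2L))
}

#' Count indel events
#'
#' An indel event is a maximal run of `-` within one row (terminal runs
#' included); events are summed over rows.
#'
#' @param aln a [alignment()] object.
#' @return integer.
#' @export
count_indel_events <- function(aln) {
  g <- aln$seq == "-"
  starts <- g & !cbind(FALSE, g[, -ncol(g), drop = FALSE])
  if (ncol(g) >= 1L) starts[, 1L] <- g[, 1L]
  sum(starts)
}

#' Relative evolutionary rate of a gene
#'
#' Defined as the gene's mean pairwise p-distance divided by a reference
#' mean pairwise distance (conventionally that of the genome-scale
#' concatenation). This distance-based proxy stands in for a tree-based
#' substitution rate; an invariant gene has rate 0.
#'
#' @param gene_aln a [alignment()] object (or a `delim_dist`).
#' @param reference_mean_distance positive reference mean distance.
#' @return non-negative scalar.
#' @export
gene_relative_rate <- function(gene_aln, reference_mean_distance) {
  if (!is.finite(reference_mean_distance) || reference_mean_distance <= 0)
    stopf("reference mean distance must be positive and finite")
  m <- if (inherits(gene_aln, "delim_dist")) mean_pairwise(gene_aln)
       else mean_pairwise(p_distance_matrix(gene_aln))
  m / reference_mean_distance
}

#' Per-gene informativeness statistics
#'
#' @param genes named list of [alignment()] objects.
#' @param reference_mean_distance reference for [gene_relative_rate()]; by
#'   default the mean pairwise distance of the concatenation of `genes`.
#' @return data.frame with columns gene, length, variable, pis, indels,
#'   rate.
#' @export
gene_stats <- function(genes, reference_mean_distance = NULL) {
  if (is.null(reference_mean_distance)) {
    conc <- concat_alignments(genes)
    reference_mean_distance <- mean_pairwise(p_distance_matrix(conc))
  }
  rows <- lapply(names(genes), function(nm) {
    g <- genes[[nm]]
    cs <- count_sites(g)
    data.frame(gene = nm, length = aln_width(g),
               variable = cs[["variable"]], pis = cs[["pis"]],
               indels = count_indel_events(g),
               rate = gene_relative_rate(g, reference_mean_distance),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intra- and inter-specific divergence summary
#'
#' Splits all sample pairs into intra (same species label) and inter
#' (different labels) categories and reports pair counts and min/mean/max
#' p-distance per category. An empty category has `n_pairs = 0` and `NA`
#' statistics.
#'
#' @param dist a `delim_dist` (or square matrix).
#' @param partition named character vector mapping every sample id in
#'   `dist` to a species label.
#' @return data.frame with rows `intra` and `inter`.
#' @export
divergence_summary <- function(dist, partition) {
  dist <- as_delim_dist(dist)
  missing <- setdiff(dist$ids, names(partition))
  if (length(missing))
    stopf("samples missing from partition: %s",
          paste(missing, collapse = ", "))
  extra <- setdiff(names(partition), dist$ids)
  if (length(extra))
    stopf("unknown sample(s) in partition: %s", paste(extra, collapse = ", "))
  lab <- partition[dist$ids]
  ut <- upper.tri(dist$d)
  same <- outer(lab, lab, "==")[ut]
  vals <- dist$d[ut]
  summarise <- function(v) {
    if (length(v) == 0L)
      return(c(n_pairs = 0, min = NA_real_, mean = NA_real_, max = NA_real_))
    c(n_pairs = length(v), min = min(v), mean = mean(v), max = max(v))
  }
  out <- rbind(intra = summarise(vals[same]), inter = summarise(vals[!same]))
  data.frame(category = rownames(out), out, row.names = NULL)
}
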