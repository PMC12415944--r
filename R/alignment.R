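#' Multiple sequence alignments with gene partitions
#'
#' An alignment is stored as an uppercase character matrix (rows = samples,
#' columns = sites) together with a partition table mapping named genes to
#' column ranges (1-based, inclusive). All alignment-consuming functions in
#' the package accept this class.
#'
#' @param seqs character matrix with unique rownames (sample ids); entries
#'   are single characters, typically `A`, `C`, `G`, `T`, `-`, `N`, `?` or
#'   IUPAC ambiguity codes. Lowercase input is uppercased.
#' @param partitions `NULL` or a data.frame with columns `gene`, `start`,
#'   `end` (1-based inclusive column indices, non-overlapping, unique gene
#'   names). `NULL` creates a single partition spanning the alignment.
#' @param name gene name used when `partitions` is `NULL`.
#' @return an object of class `delim_aln`.
#' @export
alignment <- function(seqs, partitions = NULL, name = "gene1") {
  if (!is.matrix(seqs) || !is.character(seqs))
    stopf("'seqs' must be a character matrix")
  if (is.null(rownames(seqs)) || anyDuplicated(rownames(seqs)))
    stopf("'seqs' must have unique rownames (sample ids)")
  seqs <- toupper(seqs)
  w <- ncol(seqs)
  if (is.null(partitions)) {
    partitions <- data.frame(gene = name, start = 1L, end = w,
                             stringsAsFactors = FALSE)
  }
  check_partitions(partitions, w)
  structure(list(seq = seqs, partitions = partitions), class = "delim_aln")
}

check_partitions <- function(p, width) {
  stopifnot(is.data.frame(p), all(c("gene", "start", "end") %in% names(p)))
  if (anyDuplicated(p$gene)) stopf("duplicate gene names in partitions")
  if (any(p$start < 1L) || any(p$end > width) || any(p$start > p$end))
    stopf("partition ranges must satisfy 1 <= start <= end <= %d", width)
  cols <- unlist(Map(seq.int, p$start, p$end))
  if (anyDuplicated(cols)) stopf("partitions overlap")
  invisible(p)
}

#' @export
print.delim_aln <- function(x, ...) {
  cat(sprintf("Alignment: %d samples x %d sites, %d gene partition(s)\n",
              nrow(x$seq), ncol(x$seq), nrow(x$partitions)))
  invisible(x)
}

#' @rdname alignment
#' @param x a `delim_aln` object.
#' @export
n_samples <- function(x) nrow(x$seq)

#' @rdname alignment
#' @export
aln_width <- function(x) ncol(x$seq)

#' @rdname alignment
#' @export
sample_ids <- function(x) rownames(x$seq)

#' Read one FASTA alignment file
#'
#' Sample ids are taken from the header token before the first whitespace;
#' sequences are uppercased. A non-rectangular file or a duplicated id is a
#' format error naming the file (and the offending id).
#'
#' @param path path to a FASTA file.
#' @param name gene name for the partition record (default: file base name
#'   without extension).
#' @return a [alignment()] object.
#' @export
read_fasta_alignment <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             as.string = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stopf("duplicate sample id '%s' in %s", ids[duplicated(ids)][1], path)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1L) {
    bad <- ids[which(lens != lens[1])[1]]
    stopf("ragged alignment in %s: sequence '%s' has length %d, expected %d",
          path, bad, lens[ids == bad][1], lens[1])
  }
  m <- do.call(rbind, lapply(recs, as.character))
  rownames(m) <- ids
  alignment(m, name = name)
}

#' Read a set of per-gene FASTA alignments
#'
#' @param paths character vector of FASTA file paths.
#' @param names optional gene names, one per file.
#' @return a named list of [alignment()] objects.
#' @export
read_gene_alignments <- function(paths, names = NULL) {
  if (is.null(names)) names <- sub("\\.[^.]*$", "", basename(paths))
  out <- Map(read_fasta_alignment, paths, names)
  names(out) <- names
  out
}

#' Write an alignment to FASTA (80-column wrap)
#'
#' @param aln a `delim_aln` object.
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln$seq)), function(i) aln$seq[i, ]),
    names = rownames(aln$seq), file.out = path, nbchar = 80)
  invisible(path)
}

#' Write the partition table
#'
#' `format = "raxml"` writes lines `DNA, gene = start-end` (1-based,
#' inclusive); `format = "tsv"` writes a three-column table.
#'
#' @param aln a `delim_aln` object.
#' @param path output file.
#' @param format `"raxml"` or `"tsv"`.
#' @export
write_partitions <- function(aln, path, format = c("raxml", "tsv")) {
  format <- match.arg(format)
  p <- aln$partitions
  if (format == "raxml") {
    writeLines(sprintf("DNA, %s = %d-%d", p$gene, p$start, p$end), path)
  } else {
    utils::write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are concatenated in the given order or in a seeded uniform random
#' order (the randomisation device of the gene-to-genome scaling
#' experiment). Samples missing from a gene are padded with `-` across that
#' gene's columns, which is safe downstream because distances use pairwise
#' deletion.
#'
#' @param genes non-empty list of `delim_aln` objects; each contributes one
#'   partition named after its (unique) gene name.
#' @param order `"given"` or `"random"`.
#' @param seed integer seed used when `order = "random"`.
#' @return a `delim_aln` whose width is the sum of gene widths.
#' @export
concat_alignments <- function(genes, order = c("given", "random"),
                              seed = NULL) {
  order <- match.arg(order)
  if (length(genes) == 0L) stopf("empty gene list")
  gene_names <- vapply(genes, function(g) g$partitions$gene[1], character(1))
  if (!is.null(names(genes)) && all(nzchar(names(genes))))
    gene_names <- names(genes)
  if (anyDuplicated(gene_names)) stopf("duplicate gene names")
  idx <- seq_along(genes)
  if (order == "random") idx <- with_seed_opt(seed, sample(idx))
  ids <- unique(unlist(lapply(genes, sample_ids)))
  widths <- vapply(genes, aln_width, integer(1))
  total <- sum(widths[idx])
  m <- matrix("-", nrow = length(ids), ncol = total,
              dimnames = list(ids, NULL))
  starts <- cumsum(c(1L, widths[idx][-length(idx)]))
  for (k in seq_along(idx)) {
    g <- genes[[idx[k]]]
    cols <- starts[k]:(starts[k] + aln_width(g) - 1L)
    m[sample_ids(g), cols] <- g$seq
  }
  parts <- data.frame(gene = gene_names[idx], start = starts,
                      end = starts + widths[idx] - 1L,
                      stringsAsFactors = FALSE)
  alignment(m, partitions = parts)
}

#' Split a concatenated alignment back into its gene blocks
#'
#' Inverse of [concat_alignments()] under `order = "given"`.
#'
#' @param aln a `delim_aln` with partitions.
#' @return a named list of single-gene alignments.
#' @export
split_by_partition <- function(aln) {
  p <- aln$partitions
  out <- lapply(seq_len(nrow(p)), function(i) {
    alignment(aln$seq[, p$start[i]:p$end[i], drop = FALSE],
              name = p$gene[i])
  })
  names(out) <- p$gene
  out
}

#' Collapse identical haplotypes
#'
#' Rows that are identical as exact strings (gaps and ambiguities included)
#' are collapsed onto the first-occurring representative. Deduplication
#' before tree-based delimitation avoids zero-length branches; the returned
#' map allows species memberships to be re-expanded afterwards.
#'
#' @param aln a `delim_aln` object.
#' @return a list with elements `alignment` (the deduplicated alignment)
#'   and `map` (named list: representative id -> character vector of the
#'   ids collapsed onto it; empty vectors for unique haplotypes).
#' @export
dedup_haplotypes <- function(aln) {
  keys <- apply(aln$seq, 1L, paste0, collapse = "")
  first <- !duplicated(keys)
  reps <- rownames(aln$seq)[first]
  map <- lapply(seq_along(reps), function(i) {
    dup <- keys == keys[first][i] & !first
    rownames(aln$seq)[dup]
  })
  names(map) <- reps
  out <- alignment(aln$seq[first, , drop = FALSE],
                   partitions = aln$partitions)
  list(alignment = out, map = map)
}

#' Write a haplotype map as TSV
#' @param map the `map` element returned by [dedup_haplotypes()].
#' @param path output file.
#' @export
write_haplotype_map <- function(map, path) {
  df <- data.frame(representative = names(map),
                   collapsed = vapply(map, paste, character(1),
                                      collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alignment sizes of the scaling ladder
#'
#' Target lengths are `round(10^e)` (round-half-to-even) for exponents from
#' `e_min` to `e_max` in steps of `step`; the default grid spans 316 nt
#' (10^2.5) to 100,000 nt (10^5) in steps of 0.25, giving 11 rungs.
#'
#' @param e_min,e_max,step exponent grid parameters (`e_min <= e_max`,
#'   `step > 0`).
#' @return strictly increasing integer vector of target lengths.
#' @export
size_ladder <- function(e_min = 2.5, e_max = 5.0, step = 0.25) {
  stopifnot(e_min <= e_max, step > 0)
  lens <- as.integer(round(10^seq(e_min, e_max, by = step)))
  if (any(diff(lens) <= 0L)) stopf("ladder lengths are not strictly increasing")
  lens
}

#' Take a prefix sub-alignment
#'
#' Returns the first `min(L, width)` columns, with partitions clipped to
#' the window. Prefixes of the same alignment are nested, so the scaling
#' experiment's sub-alignments differ between replicates only through the
#' randomised gene order.
#'
#' @param aln a `delim_aln` object.
#' @param L target length, `>= 1`.
#' @export
subset_prefix <- function(aln, L) {
  if (!is.numeric(L) || L < 1) stopf("prefix length must be >= 1")
  L <- min(as.integer(L), aln_width(aln))
  p <- aln$partitions
  keep <- p$start <= L
  p <- p[keep, , drop = FALSE]
  p$end <- pmin(p$end, L)
  alignment(aln$seq[, seq_len(L), drop = FALSE], partitions = p)
}
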