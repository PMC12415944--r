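test_that("p-distances follow the pairwise-deletion rule", {
  a <- aln_from_strings(c("ACGT", "ACGA"), c("s1", "s2"))
  expect_equal(p_distance_matrix(a)$d["s1", "s2"], 0.25)
  b <- aln_from_strings(c("AC-T", "ACTT"), c("s1", "s2"))
  pd <- p_distance_matrix(b)
  expect_equal(pd$d["s1", "s2"], 0)        # gap column excluded
  expect_equal(pd$overlap["s1", "s2"], 3L)
  ident <- aln_from_strings(c("ACGT", "ACGT"), c("s1", "s2"))
  expect_equal(p_distance_matrix(ident)$d["s1", "s2"], 0)
  # ambiguity codes are missing data too
  amb <- aln_from_strings(c("ARGT", "AAGT"), c("s1", "s2"))
  expect_equal(p_distance_matrix(amb)$overlap["s1", "s2"], 3L)
})

test_that("p-distance matrices are well-formed on random alignments", {
  set.seed(1)
  m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 8 * 60, TRUE,
                     prob = c(rep(0.23, 4), 0.05, 0.03)), nrow = 8)
  rownames(m) <- paste0("s", 1:8)
  pd <- p_distance_matrix(alignment(m))
  expect_true(isSymmetric(pd$d))
  expect_true(all(diag(pd$d) == 0))
  expect_true(all(pd$d >= 0 & pd$d <= 1))
  expect_true(isSymmetric(pd$overlap * 1.0))
})

test_that("p-distances agree with the reference implementation", {
  set.seed(2)
  m <- matrix(sample(c("a", "c", "g", "t"), 6 * 200, TRUE), nrow = 6)
  rownames(m) <- paste0("s", 1:6)
  ours <- p_distance_matrix(alignment(toupper(m)))$d
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
})

test_that("overlap below min_overlap errors naming the pair", {
  a <- aln_from_strings(c("A---", "-CGT"), c("s1", "s2"))
  expect_error(p_distance_matrix(a), "s1, s2")
})

test_that("site counting distinguishes variable from parsimony-informative", {
  a <- aln_from_strings(c("AAC", "AAC", "CAA", "CCA"),
                        c("s1", "s2", "s3", "s4"))
  # col1 (A,A,C,C): variable + PIS; col2 (A,A,A,C): variable only;
  # col3 (C,C,A,A): variable + PIS
  cs <- count_sites(a)
  expect_equal(cs[["variable"]], 3L)
  expect_equal(cs[["pis"]], 2L)
  # gaps/ambiguities are missing: a column A,A,-,- is not variable
  b <- aln_from_strings(c("A", "A", "-", "-"), paste0("s", 1:4))
  expect_equal(unname(count_sites(b)), c(0L, 0L))
})

test_that("PIS and variable counts respect their ordering and additivity", {
  set.seed(3)
  genes <- lapply(1:4, function(i) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 6 * 40, TRUE), nrow = 6)
    rownames(m) <- paste0("s", 1:6)
    alignment(m, name = paste0("g", i))
  })
  counts <- vapply(genes, count_sites, integer(2))
  for (i in 1:4) {
    expect_lte(counts["pis", i], counts["variable", i])
    expect_lte(counts["variable", i], 40L)
  }
  conc <- count_sites(concat_alignments(genes))
  expect_equal(conc[["pis"]], sum(counts["pis", ]))
  expect_equal(conc[["variable"]], sum(counts["variable", ]))
})

test_that("indel events count maximal gap runs per row", {
  expect_equal(count_indel_events(aln_from_strings("ACGT")), 0L)
  expect_equal(count_indel_events(aln_from_strings("A--A-")), 2L)
  expect_equal(count_indel_events(aln_from_strings(c("A-A", "A-A"))), 2L)
  expect_equal(count_indel_events(aln_from_strings("----")), 1L)
})

test_that("relative gene rates are distance ratios", {
  g <- aln_from_strings(c("ACGT", "ACGA", "ACTT"), paste0("s", 1:3))
  mg <- mean(p_distance_matrix(g)$d[upper.tri(diag(3))])
  expect_equal(gene_relative_rate(g, mg), 1.0)
  expect_equal(gene_relative_rate(g, mg / 2), 2.0)
  invariant <- aln_from_strings(c("AAAA", "AAAA", "AAAA"), paste0("s", 1:3))
  expect_equal(gene_relative_rate(invariant, 0.1), 0)
  expect_error(gene_relative_rate(g, 0), "positive")
})

test_that("divergence summaries split pairs by partition", {
  a <- aln_from_strings(c("AAAA", "AAAT", "CCCC", "CCCG"), paste0("s", 1:4))
  pd <- p_distance_matrix(a)
  part <- c(s1 = "x", s2 = "x", s3 = "y", s4 = "y")
  ds <- divergence_summary(pd, part)
  expect_equal(ds$n_pairs, c(2, 4))
  expect_equal(ds$max[1], 0.25)
  expect_equal(ds$min[2], 1.0)  # every cross pair differs at all 4 sites
  one <- divergence_summary(pd, c(s1 = "z", s2 = "z", s3 = "z", s4 = "z"))
  expect_equal(one$n_pairs[one$category == "inter"], 0)
  singl <- divergence_summary(pd, setNames(paste0("u", 1:4), paste0("s", 1:4)))
  expect_equal(singl$n_pairs[singl$category == "intra"], 0)
  expect_true(is.na(singl$mean[singl$category == "intra"]))
  expect_error(divergence_summary(pd, part[1:3]), "missing")
})

test_that("merging species moves pairs from inter to intra only", {
  set.seed(4)
  m <- matrix(sample(c("A", "C", "G", "T"), 10 * 50, TRUE), nrow = 10)
  rownames(m) <- paste0("s", 1:10)
  pd <- p_distance_matrix(alignment(m))
  for (rep in 1:20) {
    labs <- sample(letters[1:4], 10, TRUE)
    names(labs) <- paste0("s", 1:10)
    base <- divergence_summary(pd, labs)
    merged <- labs
    pick <- sample(unique(labs), 2)
    merged[merged == pick[2]] <- pick[1]
    after <- divergence_summary(pd, merged)
    if (base$n_pairs[1] > 0 && after$n_pairs[1] > 0)
      expect_gte(after$max[1], base$max[1])
    if (base$n_pairs[2] > 0 && after$n_pairs[2] > 0)
      expect_gte(after$min[2], base$min[2])
  }
})

test_that("gene_stats assembles the per-gene table", {
  ds <- generate_dataset(toy_config(seed = 10))
  gs <- gene_stats(ds$genes[1:5])
  expect_equal(nrow(gs), 5L)
  expect_true(all(gs$pis <= gs$variable))
  expect_true(all(gs$rate >= 0))
})
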