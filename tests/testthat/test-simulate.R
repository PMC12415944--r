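test_that("Yule species trees honour size, height and determinism", {
  t1 <- yule_species_tree(1)
  expect_equal(ape::Ntip(t1), 1L)
  expect_equal(sum(t1$edge.length), 0)
  t2 <- yule_species_tree(2, root_height = 0.03, seed = 1)
  expect_equal(unname(max(ape::branching.times(t2))), 0.03)
  a <- yule_species_tree(5, root_height = 0.05, seed = 9)
  b <- yule_species_tree(5, root_height = 0.05, seed = 9)
  expect_identical(write_newick(a), write_newick(b))
  expect_error(yule_species_tree(3, birth_rate = 0), "birth_rate")
})

test_that("min_split conditioning bounds the youngest species split", {
  for (s in 1:5) {
    tr <- yule_species_tree(7, root_height = 0.04, min_split = 0.016,
                            seed = s)
    expect_gte(min(ape::branching.times(tr)), 0.016)
    expect_equal(unname(max(ape::branching.times(tr))), 0.04)
  }
})

test_that("theta -> 0 collapses the gene tree onto the species tree", {
  sp <- yule_species_tree(4, root_height = 0.05, seed = 3)
  gt <- msc_genealogy(sp, rep(1L, 4), theta = 0, seed = 1)
  expect_equal(ape::Ntip(gt), 4L)
  # one sample per species, no coalescent variance: same pairwise depths
  d_sp <- cophenetic(sp)
  d_gt <- cophenetic(gt)
  rownames(d_gt) <- colnames(d_gt) <- sub("_1$", "", rownames(d_gt))
  expect_equal(d_gt[rownames(d_sp), colnames(d_sp)], d_sp, tolerance = 1e-9)
})

test_that("between-species coalescences predate the species root", {
  sp <- yule_species_tree(2, root_height = 0.02, seed = 2)
  ages <- replicate(50, {
    gt <- msc_genealogy(sp, c(1L, 1L), theta = 0.01)
    max(ape::branching.times(gt))
  })
  expect_true(all(ages >= 0.02 - 1e-12))
})

test_that("single-population TMRCA matches the coalescent expectation", {
  # E[TMRCA] = theta (1 - 1/n) in pairwise-divergence units of theta/2 per
  # pair; with rate j(j-1)/theta the expectation is theta (1 - 1/n)
  sp <- yule_species_tree(1)
  n <- 5
  theta <- 0.01
  set.seed(42)
  tm <- replicate(2000, max(ape::branching.times(
    msc_genealogy(sp, n, theta))))
  expected <- theta * (1 - 1 / n)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("JC evolution matches its closed-form expected p-distance", {
  two <- read_newick("(a:0.025,b:0.025);")  # path length 0.05
  a <- evolve_jc(two, n_sites = 10000, seed = 5)
  p_obs <- mean(a$seq["a", ] != a$seq["b", ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("JC degenerate rates behave as expected", {
  two <- read_newick("(a:0.5,b:0.5);")
  a0 <- evolve_jc(two, 200, rate_multiplier = 0, seed = 1)
  expect_identical(a0$seq["a", ], a0$seq["b", ])
  asat <- evolve_jc(two, 20000, rate_multiplier = 50, seed = 2)
  p <- mean(asat$seq["a", ] != asat$seq["b", ])
  expect_lt(abs(p - 0.75), 0.02)  # saturation limit
})

test_that("generate_dataset does the bookkeeping and is byte-deterministic", {
  cfg <- toy_config(seed = 4)
  ds <- generate_dataset(cfg)
  expect_equal(n_samples(ds$alignment), 15L)
  expect_equal(aln_width(ds$alignment), sum(cfg$gene_lengths))
  expect_equal(nrow(ds$alignment$partitions), cfg$n_genes)
  expect_length(ds$truth, 15L)
  expect_equal(sort(unique(ds$truth)), paste0("sp", 1:5))
  ds2 <- generate_dataset(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta_alignment(ds$alignment, f1)
  write_fasta_alignment(ds2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("deeper species trees give larger pairwise divergences", {
  shallow <- generate_dataset(toy_config(seed = 6, root_height = 0.01,
                                         min_split = 0.002))
  deep <- generate_dataset(toy_config(seed = 6, root_height = 0.08,
                                      min_split = 0.016))
  m_shallow <- mean(p_distance_matrix(shallow$alignment)$d)
  m_deep <- mean(p_distance_matrix(deep$alignment)$d)
  expect_gt(m_deep, m_shallow)
})

test_that("unique haplotypes are non-decreasing along nested prefixes", {
  ds <- generate_dataset(toy_config(seed = 8))
  n_uniq <- vapply(c(100L, 500L, 2000L, 5000L), function(L)
    n_samples(dedup_haplotypes(subset_prefix(ds$alignment, L))$alignment),
    integer(1))
  expect_true(all(diff(n_uniq) >= 0))
})

test_that("short prefixes carry more duplicate haplotypes than full length", {
  more_dups <- vapply(1:10, function(s) {
    ds <- generate_dataset(toy_config(seed = 20 + s))
    full <- n_samples(dedup_haplotypes(ds$alignment)$alignment)
    short <- n_samples(dedup_haplotypes(
      subset_prefix(ds$alignment, 316L))$alignment)
    short < full
  }, logical(1))
  expect_gte(median(more_dups), 1)  # short prefixes lose haplotypes
})

test_that("config validation catches inconsistent inputs", {
  expect_error(sim_config(n_genes = 3, rate_multipliers = c(1, 2)),
               "length n_genes")
  expect_error(sim_config(theta = -1), ">= 0")
  expect_warning(sim_config(root_height = 0.001, theta = 0.01,
                            min_split = 0), "root_height <= theta")
})
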