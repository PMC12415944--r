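test_that("lineage classification follows the threshold rule", {
  toy <- read_newick("((a:0.01,b:0.01):0.09,(c:0.01,d:0.01):0.09);")
  cl <- classify_lineages(toy, 0.05)
  expect_length(cl$clusters, 2L)
  expect_length(cl$singletons, 0L)
  expect_true(same_partition(cl$partition,
                             c(a = "x", b = "x", c = "y", d = "y")))
  # T above the root: one all-encompassing cluster
  all_one <- classify_lineages(toy, 1)
  expect_length(all_one$clusters, 1L)
  # T below every node: all tips singletons
  singls <- classify_lineages(toy, 0.001)
  expect_length(singls$clusters, 0L)
  expect_length(singls$singletons, 4L)
  expect_error(classify_lineages(read_newick("((a:1,b:2):1,c:2);"), 0.5),
               "ultrametric")
})

test_that("the mixed likelihood matches hand-computed values", {
  # pure diversification on a 3-tip tree: logL = sum log n_i - sum n_i x_i
  tr3 <- read_newick("((a:0.5,b:0.5):0.5,c:1);")
  expect_equal(gmyc_loglik(tr3, 0, 1, 1, 5, 1), log(6) - 2.5,
               tolerance = 1e-9)
  # mixed classes on the 5-tip fixture at T = 0.12: clusters {a,b}, {c,d},
  # singleton e; four intervals evaluated by hand
  tr5 <- tree5()
  lz <- 2; pz <- 1.3; lc <- 40; pc <- 0.8
  b1 <- lz * 1^pz + lc * (2^pc + 2^pc)
  b2 <- lz * 2^pz + lc * 2^pc
  b3 <- lz * 3^pz
  b4 <- lz * 2^pz
  hand <- 2 * log(lc * 2^pc) + log(lz * 3^pz) + log(lz * 2^pz) -
    (0.05 * b1 + 0.05 * b2 + 0.1 * b3 + 0.8 * b4)
  expect_equal(gmyc_loglik(tr5, 0.12, lz, pz, lc, pc), hand,
               tolerance = 1e-9)
})

test_that("the likelihood obeys the age/rate change-of-variables identity", {
  tr5 <- tree5()
  cc <- 3.7
  scaled <- tr5
  scaled$edge.length <- scaled$edge.length * cc
  v <- gmyc_loglik(tr5, 0.12, 2, 1.3, 40, 0.8)
  v_scaled <- gmyc_loglik(scaled, 0.12 * cc, 2 / cc, 1.3, 40 / cc, 0.8)
  expect_equal(v_scaled, v - 4 * log(cc), tolerance = 1e-8)
})

test_that("a threshold above the root reduces to the single coalescent", {
  tr5 <- tree5()
  above <- max(ape::branching.times(tr5)) * 1.01
  # whole tree one cluster: only the coalescent class contributes
  v_mixed <- gmyc_loglik(tr5, above, 7, 2, 3, 0.9)
  tbl <- delimscale:::gmyc_interval_table(tr5, above)
  n_r <- 5 - (seq_len(4) - 1L)
  pair <- n_r * (n_r - 1)
  v_null <- sum(log(3 * pair^0.9)) - sum(3 * pair^0.9 * tbl$x)
  expect_equal(v_mixed, v_null, tolerance = 1e-9)
})

test_that("zero rates with events present give -Inf, not an error", {
  expect_identical(gmyc_loglik(tree5(), 0, 0, 1, 0, 1), -Inf)
})

test_that("GMYC fitting recovers well-separated species as entities", {
  # stem/crown ratio 50: five 3-tip clusters with deep stems
  tr <- species_tree_fixture(k = 5, crown = 0.002, stem = 0.1)
  expect_true(ape::is.ultrametric(tr))
  fit <- fit_gmyc(tr, seed = 1)
  expect_equal(fit$n_entities, 5L)
  expect_equal(fit$n_clusters, 5L)
  expect_gte(fit$logL_mixed, fit$logL_null - 1e-6)
  expect_gte(fit$LR, -1e-6)
  truth <- setNames(rep(paste0("sp", 1:5), each = 3),
                    paste0("s", rep(1:5, each = 3), "_", rep(1:3, 5)))
  expect_true(same_partition(fit$partition, truth))
})

test_that("the fitted coalescent rate is at a likelihood maximum", {
  tr <- species_tree_fixture(k = 5, crown = 0.002, stem = 0.1)
  fit <- fit_gmyc(tr, seed = 2)
  expect_gte(fit$n_clusters, 1L)  # coalescent class genuinely in play
  base <- gmyc_loglik(tr, fit$threshold, fit$lambda_z, fit$p_z,
                      fit$lambda_coal, fit$p_c)
  for (f in c(0.8, 0.9, 1.1, 1.25)) {
    expect_lte(gmyc_loglik(tr, fit$threshold, fit$lambda_z, fit$p_z,
                           fit$lambda_coal * f, fit$p_c), base + 1e-6)
    expect_lte(gmyc_loglik(tr, fit$threshold, fit$lambda_z * f, fit$p_z,
                           fit$lambda_coal, fit$p_c), base + 1e-6)
  }
})

test_that("entity counts decrease monotonically in the threshold", {
  tr <- species_tree_fixture(k = 4, crown = 0.003, stem = 0.05)
  fit <- fit_gmyc(tr, seed = 3)
  cand <- fit$candidates[order(fit$candidates$threshold), ]
  expect_true(all(diff(cand$n_entities) <= 0))
  expect_equal(max(cand$n_entities), ape::Ntip(tr))
  expect_equal(min(cand$n_entities), 1L)
})

test_that("equal node ages trigger the degeneracy warning", {
  star <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  star$edge.length <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  # comb with all ages equal: build explicitly
  eq <- read_newick("((a:0.1,b:0.1):0,(c:0.1,d:0.1):0);")
  w <- testthat::capture_warnings(fit <- fit_gmyc(eq, seed = 1))
  expect_true(any(grepl("degenerate", w)))
  expect_true(fit$n_entities %in% c(1L, 4L))
})

test_that("the Moran estimator matches its closed form and mechanism", {
  expect_equal(moran_lambda(read_newick("(a:0.25,b:0.25);")), 1 / (2 * 0.25))
  # halving all waiting times doubles the estimate
  tr <- species_tree_fixture(k = 3, crown = 0.01, stem = 0.05)
  half <- tr
  half$edge.length <- half$edge.length / 2
  expect_equal(moran_lambda(half), 2 * moran_lambda(tr), tolerance = 1e-9)
  zero <- read_newick("((a:0,b:0):0,c:0);")
  expect_warning(expect_identical(moran_lambda(zero), Inf), "zero")
})
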