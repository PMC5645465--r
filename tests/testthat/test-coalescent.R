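test_that("pairwise coalescence time is Exponential(1) on average", {
  withr::local_seed(31)
  times <- replicate(2000, max(simulate_genealogy(2)$time))
  expect_equal(mean(times), 1.0, tolerance = 0.08)  # ~4 SE at R = 2000
  expect_error(simulate_genealogy(1), "n >= 2")
})

test_that("genealogies are exactly reproducible under a seed", {
  t1 <- simulate_genealogy(30, seed = 99)
  t2 <- simulate_genealogy(30, seed = 99)
  expect_identical(t1, t2)
  m1 <- sprinkle_fixed_s(t1, 10, seed = 5)
  m2 <- sprinkle_fixed_s(t2, 10, seed = 5)
  expect_identical(m1$alleles, m2$alleles)
})

test_that("tree bookkeeping is internally consistent", {
  withr::local_seed(32)
  tree <- simulate_genealogy(25)
  expect_equal(sum(tree$parent == 0L), 1L)              # single root
  expect_equal(tree$n_desc[length(tree$n_desc)], 25L)   # root subtends all
  expect_true(all(tree$length[tree$parent > 0L] > 0))
  # branch lengths sum to sum over epochs of k * t_k
  expect_equal(total_branch_length(tree),
               sum(tree$length), tolerance = 1e-12)
})

test_that("fixed-S sprinkling yields exactly S polymorphic sites", {
  withr::local_seed(33)
  for (rep in 1:10) {
    tree <- simulate_genealogy(12)
    m <- sprinkle_fixed_s(tree, 15, seq_length = 500L)
    expect_equal(n_sites(m), 15L)
    counts <- colSums(m$alleles)
    expect_true(all(counts >= 1 & counts <= 11))  # never monomorphic
  }
  # n = 2: every mutation separates the pair
  tree2 <- simulate_genealogy(2, seed = 1)
  m2 <- sprinkle_fixed_s(tree2, 7, seed = 2)
  expect_equal(unname(rowSums(m2$alleles == 1L) + rowSums(m2$alleles == 0L)),
               c(7L, 7L))
  expect_equal(sum(m2$alleles[1, ] != m2$alleles[2, ]), 7L)
  expect_error(sprinkle_fixed_s(tree2, 0), "S must be")
})

test_that("mutations land on branches proportionally to length", {
  # two leaves: each branch carries its share of mutations ~ length share
  tree <- simulate_genealogy(3, seed = 17)
  share <- tree$length / sum(tree$length)
  # singleton fraction over replicates estimates the external-branch share
  withr::local_seed(19)
  singletons <- replicate(300, {
    m <- sprinkle_fixed_s(tree, 4)
    mean(colSums(m$alleles) == 1L)
  })
  ext_share <- sum(share[1:3])
  expect_equal(mean(singletons), ext_share, tolerance = 0.05)
})

test_that("empirical p-values use the add-one rule", {
  null <- structure(list(statistic = "D", values = c(-1, 0, 1), n = 4, S = 1,
                         R = 3L, seed = NULL), class = "null_distribution")
  expect_equal(empirical_p(-0.5, null, "lower"), (1 + 1) / (3 + 1))
  expect_equal(empirical_p(0, null, "two-sided"), 1)
  big <- structure(list(statistic = "D", values = seq_len(999), n = 4, S = 1,
                        R = 999L, seed = NULL), class = "null_distribution")
  expect_equal(empirical_p(0, big, "lower"), 1 / 1000)
})

test_that("null CI follows type-7 quantiles and widens with level", {
  null <- structure(list(statistic = "D", values = as.numeric(1:100),
                         n = 4, S = 1, R = 100L, seed = NULL),
                    class = "null_distribution")
  ci <- null_ci(null)
  expect_equal(ci$low, 3.475)
  expect_equal(ci$high, 97.525)
  const <- structure(list(statistic = "D", values = rep(2, 50), n = 4,
                          S = 1, R = 50L, seed = NULL),
                     class = "null_distribution")
  cc <- null_ci(const)
  expect_equal(c(cc$low, cc$high), c(2, 2))
  wide <- null_ci(null, 0.99)
  expect_lte(wide$low, ci$low)
  expect_gte(wide$high, ci$high)
  small <- structure(list(statistic = "D", values = 1:10, n = 4, S = 1,
                          R = 10L, seed = NULL), class = "null_distribution")
  expect_warning(null_ci(small), "unstable")
})

test_that("null distributions are seeded and finite", {
  nd <- null_distribution(10, 5, R = 50, statistic = "D", seed = 77)
  nd2 <- null_distribution(10, 5, R = 50, statistic = "D", seed = 77)
  expect_identical(nd$values, nd2$values)
  expect_true(all(is.finite(nd$values)))
  expect_equal(length(null_distribution(10, 5, R = 1, seed = 1)$values), 1L)
  expect_error(null_distribution(3, 5, statistic = "D"), "n >= 4")
})

test_that("null_test wires p, CI and tidiers together", {
  nt <- null_test(-2, n = 20, S = 10, R = 200, statistic = "D",
                  tail = "lower", seed = 42)
  expect_equal(nt$p.value, empirical_p(-2, nt$null, "lower"))
  td <- generics::tidy(nt)
  expect_equal(td$observed, -2)
  expect_true(all(c("ci_low", "ci_high", "p.value") %in% names(td)))
})
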