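mk_geno <- function(al, contig = "nuc", len = 100000L) {
  variant_matrix(al, sort(sample.int(len, ncol(al))), contig, len)
}

test_that("genotype preparation applies the count and missingness floors", {
  withr::local_seed(61)
  n <- 150
  al <- cbind(
    c(rep(1L, 2), rep(0L, n - 2)),                 # 2 alt copies -> removed
    c(rep(1L, 3), rep(0L, n - 3)),                 # 3 copies -> kept
    c(rep(NA, 16), rbinom(n - 16, 1, 0.4)),        # 10.7% missing -> removed
    c(rep(NA, 15), rbinom(n - 15, 1, 0.4))         # exactly 10% -> kept
  )
  m <- variant_matrix(al, c(10L, 20L, 30L, 40L), "nuc", 1000L)
  g <- prepare_genotypes(m)
  expect_equal(g$positions, c(20L, 40L))
  # regions restriction and the empty-region contract
  g2 <- prepare_genotypes(m, genomic_intervals("nuc", 15L, 25L))
  expect_equal(g2$positions, 20L)
  g3 <- prepare_genotypes(m, genomic_intervals())
  expect_equal(n_sites(g3), 0L)
})

test_that("prepared set matches a hand enumeration on a 20-SNP fixture", {
  withr::local_seed(62)
  n <- 50
  al <- matrix(rbinom(n * 20, 1L, runif(20, 0.01, 0.5)[rep(1:20, each = n)]),
               nrow = n)
  al[sample(length(al), 60)] <- NA
  keep_col <- colSums(!is.na(al)) > 0
  al <- al[, keep_col, drop = FALSE]
  m <- variant_matrix(al, sort(sample.int(5000L, ncol(al))), "nuc", 5000L)
  g <- prepare_genotypes(m, min_count = 3, max_missing = 0.10)
  hand <- vapply(seq_len(ncol(al)), function(s) {
    col <- al[, s]
    miss <- mean(is.na(col))
    cnt <- min(sum(col == 1, na.rm = TRUE), sum(col == 0, na.rm = TRUE))
    miss <= 0.10 && cnt >= 3
  }, TRUE)
  expect_equal(g$positions, m$positions[hand])
})

test_that("single-trait regression matches lm per SNP", {
  withr::local_seed(63)
  n <- 60
  al <- matrix(rbinom(n * 5, 1L, 0.3), nrow = n)
  al[sample(length(al), 20)] <- NA
  G <- mk_geno(al[, colSums(!is.na(al)) > 0, drop = FALSE])
  y <- rnorm(n, sd = 2)
  res <- single_trait_assoc(G, y, min_n = 5)
  for (k in seq_len(nrow(res))) {
    s <- match(res$position[k], G$positions)
    fit <- summary(stats::lm(y ~ g, data = data.frame(y = y, g = G$alleles[, s])))
    expect_equal(res$estimate[k], fit$coefficients["g", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(res$p.value[k], fit$coefficients["g", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("a phenotype equal to the genotype gives slope 1 and floor p", {
  n <- 40
  g <- rep(c(0L, 1L), each = n / 2)
  G <- mk_geno(cbind(g))
  res <- single_trait_assoc(G, as.numeric(g))
  expect_equal(res$estimate, 1)
  expect_equal(res$p.value, .Machine$double.xmin)
})

test_that("allele-label flips negate the slope but keep |t|, p and F", {
  withr::local_seed(64)
  n <- 80
  al <- cbind(rbinom(n, 1L, 0.4))
  G <- mk_geno(al)
  Gf <- mk_geno(1L - al)
  Gf$positions <- G$positions
  y <- rnorm(n) + al[, 1]
  a <- single_trait_assoc(G, y)
  b <- single_trait_assoc(Gf, y)
  expect_equal(a$estimate, -b$estimate)
  expect_equal(abs(a$statistic), abs(b$statistic))
  expect_equal(a$p.value, b$p.value)
  Y <- cbind(y, rnorm(n))
  fa <- multivariate_assoc(G, Y)
  fb <- multivariate_assoc(Gf, Y)
  expect_equal(fa$statistic, fb$statistic)
  expect_equal(fa$p.value, fb$p.value)
})

test_that("multivariate F and p match the linear-model oracle to 1e-8", {
  withr::local_seed(65)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    g <- rbinom(n, 1L, runif(1, 0.2, 0.5))
    if (var(g) == 0) next
    Y <- matrix(rnorm(2 * n), ncol = 2)
    Y[, 1] <- Y[, 1] + g * runif(1, 0, 1.5)
    G <- mk_geno(cbind(g))
    res <- multivariate_assoc(G, Y, min_n = 5)
    # oracle: overall F of regressing genotype on the two phenotypes
    fit <- summary(stats::lm(g ~ Y))
    Fo <- unname(fit$fstatistic[1])
    po <- stats::pf(fit$fstatistic[1], fit$fstatistic[2], fit$fstatistic[3],
                    lower.tail = FALSE)
    expect_equal(res$statistic, Fo, tolerance = 1e-8)
    expect_equal(res$p.value, unname(po), tolerance = 1e-8)
    # and the canonical correlation itself
    cc <- stats::cancor(matrix(as.numeric(g), ncol = 1), Y)
    expect_equal(res$estimate, cc$cor[1], tolerance = 1e-8)
  }
})

test_that("collinear phenotypes are rejected with advice", {
  n <- 30
  G <- mk_geno(cbind(rbinom(n, 1L, 0.5)))
  y <- rnorm(n)
  expect_error(multivariate_assoc(G, cbind(y, 2 * y)), "single_trait")
})

test_that("joint testing dominates the weaker single trait when the signal is shared", {
  withr::local_seed(66)
  wins <- replicate(30, {
    n <- 100
    g <- rbinom(n, 1L, 0.3)
    if (var(g) == 0) return(NA)
    y1 <- rnorm(n)                      # noise trait
    y2 <- g + rnorm(n, sd = 0.5)        # genotype-driven trait
    G <- mk_geno(cbind(g))
    pm <- multivariate_assoc(G, cbind(y1, y2))$p.value
    ps <- single_trait_assoc(G, y1)$p.value
    pm <= ps
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.9)
})

test_that("hit reporting filters, sorts and clusters", {
  res <- tibble::tibble(
    contig = "nuc",
    position = c(1000L, 3000L, 5000L, 200000L, 203000L, 500000L),
    model = "single",
    estimate = 1, statistic = 5,
    p.value = c(1e-7, 2e-7, 5e-6, 1e-8, 8e-6, 0.5),
    p_bonferroni = 1, p_bh = 1, n_used = 100L
  )
  hits <- report_hits(res, alpha = 9e-6)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$p.value, sort(hits$p.value))
  cl <- hits[order(hits$position), ]
  expect_equal(cl$cluster, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(nrow(report_hits(dplyr::mutate(res, p.value = 0.5))), 0L)
  one <- report_hits(dplyr::mutate(res[1, ], p.value = 1e-7))
  expect_equal(nrow(one), 1L)
})

test_that("a planted 13 + 3 hit layout clusters into the dense region and satellites", {
  pos <- c(seq(13550916L, 13569038L, length.out = 13),
           5811043L, 5814103L, 2055556L)
  res <- tibble::tibble(
    contig = c(rep("2R", 15), "3L"),
    position = as.integer(pos),
    model = "multivariate", estimate = 1, statistic = 30,
    p.value = rep(1e-7, 16), p_bonferroni = 1, p_bh = 1, n_used = 167L
  )
  hits <- report_hits(res, alpha = 9e-6)
  expect_equal(nrow(hits), 16L)
  main <- hits$cluster[hits$position >= 13550916 & hits$position <= 13569038]
  expect_equal(length(unique(main)), 1L)
  expect_equal(sum(hits$cluster == unique(main)), 13L)
})
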