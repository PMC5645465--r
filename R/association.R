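#' Prepare nuclear genotypes for association testing
#'
#' Restricts a haploid-coded matrix to candidate regions (e.g. haplotype
#' blocks flagged by a prior selection scan), then applies the
#' association-grade filters: minor-allele count of at least `min_count`
#' (3 copies is about a 2% frequency floor in a 167-line panel) and
#' missing fraction at most `max_missing`. Heterozygous calls are
#' expected to have been coded missing upstream.
#'
#' @param x A [variant_matrix()].
#' @param regions Interval tibble of candidate regions; `NULL` means no
#'   restriction, an empty tibble yields an empty result.
#' @param min_count Minimum minor-allele copies (default 3).
#' @param max_missing Missingness ceiling (default 0.10, inclusive).
#' @return Filtered [variant_matrix()]; counts via [filter_report()].
#' @export
prepare_genotypes <- function(x, regions = NULL, min_count = 3L,
                              max_missing = 0.10) {
  if (!is.null(regions)) {
    regions <- merge_intervals(regions)
    inside <- rep(FALSE, n_sites(x))
    reg <- regions[regions$contig == x$contig, ]
    for (r in seq_len(nrow(reg))) {
      inside <- inside | (x$positions >= reg$start[r] &
                            x$positions <= reg$end[r])
    }
    x <- add_report(subset_sites(x, inside), filter_report(x),
                    "outside_regions", sum(!inside), sum(inside))
  }
  x <- filter_missingness(x, max_missing)
  filter_minor_count(x, min_count)
}

#' Single-trait association: phenotype on allele count
#'
#' Per-SNP least-squares regression of the phenotype on the haploid
#' 0/1 genotype, complete cases only, with a two-sided t-test on
#' `n_used - 2` degrees of freedom. SNPs with fewer than `min_n`
#' complete cases or no genotype variance after deletion are skipped
#' (counted in the `n_skipped` attribute).
#'
#' @param G Prepared [variant_matrix()] (see [prepare_genotypes()]).
#' @param y Phenotype vector, one value per sample (NA allowed).
#' @param min_n Minimum complete cases per SNP (default 10).
#' @return Tibble: contig, position, model, estimate (slope), statistic,
#'   p.value, p_bonferroni, p_bh, n_used.
#' @export
single_trait_assoc <- function(G, y, min_n = 10L) {
  stopifnot(length(y) == n_samples(G))
  res <- purrr::map_dfr(seq_len(n_sites(G)), function(s) {
    g <- G$alleles[, s]
    ok <- !is.na(g) & !is.na(y)
    n <- sum(ok)
    if (n < min_n) return(NULL)
    gv <- g[ok]; yv <- y[ok]
    if (stats::var(gv) == 0) return(NULL)
    slope <- stats::cov(gv, yv) / stats::var(gv)
    r2 <- if (stats::var(yv) == 0) 0 else stats::cor(gv, yv)^2
    tstat <- sign(slope) * sqrt(r2 / max(1 - r2, .Machine$double.eps) * (n - 2))
    p <- max(2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
             .Machine$double.xmin)
    tibble::tibble(contig = G$contig, position = G$positions[s],
                   model = "single", estimate = slope, statistic = tstat,
                   p.value = p, n_used = n)
  })
  finish_assoc(res, n_sites(G))
}

#' Multivariate association: one SNP, two phenotypes
#'
#' Per-SNP canonical correlation `rho` between the haploid genotype and
#' the two mean-centred phenotypes jointly, tested with
#' `F = ((n - 1 - k)/k) * rho^2 / (1 - rho^2)` on `(k, n - 1 - k)`
#' degrees of freedom, `k = 2`. With a single genotype vector this is
#' identical to the regression of genotype on the two phenotypes
#' (and to Wilks' exact F for one predictor).
#'
#' @param G Prepared [variant_matrix()].
#' @param Y Matrix or data frame with n rows and 2 phenotype columns.
#' @param min_n Minimum complete cases per SNP (default 10).
#' @return Tibble: contig, position, model, estimate (`rho`), statistic
#'   (F), p.value, p_bonferroni, p_bh, n_used.
#' @export
multivariate_assoc <- function(G, Y, min_n = 10L) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == n_samples(G), ncol(Y) == 2L)
  cc <- stats::complete.cases(Y)
  if (sum(cc) > 2L && abs(stats::cor(Y[cc, 1], Y[cc, 2])) >= 1 - 1e-12)
    stop("phenotypes are collinear; use single_trait_assoc instead",
         call. = FALSE)
  k <- 2L
  res <- purrr::map_dfr(seq_len(n_sites(G)), function(s) {
    g <- G$alleles[, s]
    ok <- !is.na(g) & cc
    n <- sum(ok)
    if (n < max(min_n, k + 2L)) return(NULL)
    gv <- g[ok] - mean(g[ok])
    if (sum(gv^2) == 0) return(NULL)
    Yc <- scale(Y[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    syy <- crossprod(Yc)
    sgy <- crossprod(Yc, gv)
    rho2 <- drop(crossprod(sgy, solve(syy, sgy))) / sum(gv^2)
    rho2 <- min(max(rho2, 0), 1)
    Fstat <- ((n - 1 - k) / k) * rho2 / max(1 - rho2, .Machine$double.eps)
    p <- max(stats::pf(Fstat, k, n - 1 - k, lower.tail = FALSE),
             .Machine$double.xmin)
    tibble::tibble(contig = G$contig, position = G$positions[s],
                   model = "multivariate", estimate = sqrt(rho2),
                   statistic = Fstat, p.value = p, n_used = n)
  })
  finish_assoc(res, n_sites(G))
}

finish_assoc <- function(res, n_input) {
  if (is.null(res) || nrow(res) == 0L) {
    res <- tibble::tibble(contig = character(), position = integer(),
                          model = character(), estimate = double(),
                          statistic = double(), p.value = double(),
                          n_used = integer())
  }
  res$p_bonferroni <- stats::p.adjust(res$p.value, "bonferroni")
  res$p_bh <- stats::p.adjust(res$p.value, "BH")
  res <- res[, c("contig", "position", "model", "estimate", "statistic",
                 "p.value", "p_bonferroni", "p_bh", "n_used")]
  attr(res, "n_skipped") <- n_input - nrow(res)
  res
}

#' Significant association hits with regional clustering
#'
#' Keeps rows below the fixed p-value cutoff (no further correction —
#' candidate regions are long haplotype blocks whose SNPs are far from
#' independent, so a fixed cutoff plus the reported Bonferroni/BH
#' columns is the transparent choice) and annotates clusters of hits
#' lying within `cluster_bp` of each other on the same contig.
#'
#' @param results Association tibble ([single_trait_assoc()] /
#'   [multivariate_assoc()], possibly row-bound).
#' @param alpha P-value cutoff (default 9e-6).
#' @param cluster_bp Maximum gap between hits in one cluster (default
#'   20000).
#' @return Hit tibble sorted by p, with a `cluster` id column.
#' @export
report_hits <- function(results, alpha = 9e-6, cluster_bp = 20000L) {
  hits <- dplyr::filter(results, .data$p.value < alpha)
  if (nrow(hits) == 0L) return(dplyr::mutate(hits, cluster = integer()))
  hits <- dplyr::arrange(hits, .data$contig, .data$position)
  new_cluster <- c(TRUE, diff(hits$position) > cluster_bp |
                     hits$contig[-1] != hits$contig[-nrow(hits)])
  hits$cluster <- cumsum(new_cluster)
  dplyr::arrange(hits, .data$p.value)
}
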