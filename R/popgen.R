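#' Constants for Tajima's D
#'
#' Harmonic sums and normalising coefficients for sample size `n`, as
#' introduced with the statistic (a1, a2, b1, b2, c1, c2, e1, e2).
#'
#' @param n Number of sampled sequences (>= 2; the variance terms need
#'   n >= 4 to be usable).
#' @return Named list of the eight constants plus `n`.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-site nucleotide diversity
#'
#' For a site with `m` non-missing haploid calls of which `j` carry the
#' alternate allele, the mean pairwise difference is
#' `2 j (m - j) / (m (m - 1))` — missing data is handled
#' pairwise-complete, per site.
#'
#' @param column Integer vector of 0/1/NA calls at one site.
#' @return Per-site pi; `NA` (with a warning) when fewer than two calls.
#' @export
site_pi <- function(column) {
  m <- sum(!is.na(column))
  if (m < 2L) {
    warning("site with <2 non-missing calls skipped", call. = FALSE)
    return(NA_real_)
  }
  j <- sum(column == 1L, na.rm = TRUE)
  2 * j * (m - j) / (m * (m - 1))
}

# vectorised per-site pi over all sites of a matrix (no warnings; m<2
# yields NA)
site_pi_all <- function(x) {
  al <- x$alleles
  m <- colSums(!is.na(al))
  j <- colSums(al == 1L, na.rm = TRUE)
  out <- 2 * j * (m - j) / (m * (m - 1))
  out[m < 2L] <- NA_real_
  out
}

#' Watterson's theta per site
#'
#' `S / (a1 * L)` with `S` segregating sites, `a1` the harmonic number at
#' the panel size and `L` the sequence length.
#'
#' @param x A [variant_matrix()].
#' @return Per-base Watterson estimate.
#' @export
watterson_theta <- function(x) {
  n_sites(x) / (tajima_constants(n_samples(x))$a1 * x$seq_length)
}

#' Tajima's D for a variant matrix
#'
#' `D = (Pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with `Pi` the per-locus
#' sum of [site_pi()] (pairwise-complete at each site) and the constants
#' taken at the panel sample count. Negative D flags an excess of rare
#' variants — the footprint of a recent sweep or expansion.
#'
#' @param x A [variant_matrix()] with n >= 4 samples.
#' @return D, or `NA` when `S = 0` (undefined).
#' @export
tajimas_d <- function(x) {
  n <- n_samples(x)
  if (n < 4L) stop("Tajima's D needs n >= 4", call. = FALSE)
  S <- n_sites(x)
  if (S == 0L) return(NA_real_)
  cst <- tajima_constants(n)
  Pi <- sum(site_pi_all(x), na.rm = TRUE)
  (Pi - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Diversity statistics in windows
#'
#' Tiles the contig into `window_bp` windows (1-based, last partial
#' window retained) and reports per window: segregating sites `S`,
#' per-base pi (denominator = all window bases, monomorphic included),
#' per-base Watterson's theta and Tajima's D (`NA` where `S = 0`).
#'
#' @param x A [variant_matrix()] (normally after [qc_matrix()]).
#' @param window_bp Window width in bp (default 10000).
#' @return Tibble: contig, start, end, S, pi, theta_w, D, n_eff (minimum
#'   per-site call count in the window).
#' @export
windowed_stats <- function(x, window_bp = 10000L) {
  if (window_bp <= 0L) stop("window_bp must be positive", call. = FALSE)
  starts <- seq(1L, x$seq_length, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, x$seq_length)
  pi_site <- site_pi_all(x)
  m <- colSums(!is.na(x$alleles))
  cst <- tajima_constants(n_samples(x))
  purrr::map2_dfr(starts, ends, function(s, e) {
    idx <- which(x$positions >= s & x$positions <= e)
    S <- length(idx)
    width <- e - s + 1L
    Pi <- sum(pi_site[idx], na.rm = TRUE)
    D <- if (S == 0L) NA_real_ else
      (Pi - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    tibble::tibble(
      contig = x$contig, start = s, end = e, S = S,
      pi = Pi / width,
      theta_w = S / (cst$a1 * width),
      D = D,
      n_eff = if (S) min(m[idx]) else NA_integer_
    )
  })
}

#' Genome-wide diversity summary
#'
#' Whole-contig pi, theta and D, plus the mean of defined windowed D
#' values (windows with `S = 0` excluded) — both conventions for an
#' "overall" D are reported since they can differ.
#'
#' @param x A [variant_matrix()].
#' @param window_bp Window width for the windowed mean.
#' @return One-row tibble.
#' @export
diversity_summary <- function(x, window_bp = 10000L) {
  w <- windowed_stats(x, window_bp)
  tibble::tibble(
    contig = x$contig,
    n = n_samples(x),
    S = n_sites(x),
    pi = sum(site_pi_all(x), na.rm = TRUE) / x$seq_length,
    theta_w = watterson_theta(x),
    D_overall = tajimas_d(x),
    D_window_mean = mean(w$D, na.rm = TRUE),
    windows_defined = sum(!is.na(w$D))
  )
}
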