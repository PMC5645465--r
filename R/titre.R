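#' Relative copy number (titre) of a target genome
#'
#' The titre of an organelle or endosymbiont genome is estimated as the
#' ratio of its mean read depth to the mean depth of a nuclear
#' normalisation region from the same library, optionally times a ploidy
#' factor. Masked target bases (e.g. repeated elements flagged by
#' [mask_high_coverage()]) are excluded from the target mean.
#'
#' @param target_profile [depth_profile()] on the target genome.
#' @param nuclear_profile [depth_profile()] on the nuclear normalisation
#'   region.
#' @param mask Interval tibble of target bases to exclude (default none).
#' @param ploidy_factor Multiplier on the raw depth ratio; 1 reports the
#'   plain ratio, 2 converts to copies per (diploid) cell.
#' @return One-row tibble: `sample`, `target`, `titre`,
#'   `target_mean_depth`, `nuclear_mean_depth`, `masked_bp`.
#' @export
relative_copy_number <- function(target_profile, nuclear_profile,
                                 mask = genomic_intervals(),
                                 ploidy_factor = 1.0) {
  nuc_mean <- mean(nuclear_profile$depth)
  if (nuc_mean <= 0)
    stop("undefined titre: nuclear mean depth is 0 for sample ",
         target_profile$sample, call. = FALSE)
  masked <- interval_mask(mask[mask$contig == target_profile$contig, ],
                          length(target_profile$depth))
  if (all(masked))
    stop("target contig fully masked for sample ", target_profile$sample,
         call. = FALSE)
  tgt_mean <- mean(target_profile$depth[!masked])
  tibble::tibble(
    sample = target_profile$sample,
    target = target_profile$contig,
    titre = ploidy_factor * tgt_mean / nuc_mean,
    target_mean_depth = tgt_mean,
    nuclear_mean_depth = nuc_mean,
    masked_bp = sum(masked)
  )
}

#' Titre table for a panel: mtDNA and endosymbiont per sample
#'
#' Each target genome is normalised against its own nuclear region (the
#' regions are chosen to match the target's size, so sampling noise in
#' the normaliser is comparable).
#'
#' @param panel Named list with one entry per sample; each entry a named
#'   list of [depth_profile()]s containing at least the contigs named in
#'   `targets` and `nuclear`.
#' @param targets Character vector of target contig names
#'   (default `c("mt", "endo")`).
#' @param nuclear Named character vector or list mapping each target to
#'   its nuclear normalisation profile name; a single name applies to all
#'   targets.
#' @param masks Named list of interval tibbles per target contig.
#' @param ploidy_factor Passed to [relative_copy_number()].
#' @return Tibble with one row per sample x target.
#' @export
titre_table <- function(panel, targets = c("mt", "endo"),
                        nuclear = c(mt = "nuc_mt", endo = "nuc_endo"),
                        masks = list(), ploidy_factor = 1.0) {
  if (length(nuclear) == 1L && is.null(names(nuclear)))
    nuclear <- stats::setNames(rep(nuclear, length(targets)), targets)
  purrr::imap_dfr(panel, function(profiles, sample) {
    purrr::map_dfr(targets, function(tg) {
      nk <- nuclear[[tg]]
      if (is.null(profiles[[tg]]) || is.null(profiles[[nk]]))
        stop("sample ", sample, " is missing profile '",
             if (is.null(profiles[[tg]])) tg else nk, "'", call. = FALSE)
      relative_copy_number(profiles[[tg]], profiles[[nk]],
                           mask = masks[[tg]] %||% genomic_intervals(),
                           ploidy_factor = ploidy_factor)
    })
  })
}

#' Relationship between mtDNA and endosymbiont titres
#'
#' Least-squares regression of endosymbiont titre on mtDNA titre plus the
#' product-moment correlation, with a two-sided t-test on n - 2 degrees
#' of freedom. A positive relationship is the signature of shared host
#' control over cytoplasmic genome copy number.
#'
#' @param mt,endo Equal-length titre vectors (n >= 3).
#' @return An object of class `titre_fit`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @export
titre_relationship <- function(mt, endo) {
  stopifnot(length(mt) == length(endo))
  n <- length(mt)
  if (n < 3L) stop("need at least 3 paired titres", call. = FALSE)
  if (stats::sd(mt) == 0 || stats::sd(endo) == 0)
    stop("zero variance in a titre vector", call. = FALSE)
  r <- stats::cor(mt, endo)
  slope <- r * stats::sd(endo) / stats::sd(mt)
  intercept <- mean(endo) - slope * mean(mt)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(n = n, slope = slope, intercept = intercept,
                 correlation = r, statistic = tstat, p.value = p,
                 data = tibble::tibble(mt = mt, endo = endo)),
            class = "titre_fit")
}

#' @export
print.titre_fit <- function(x, ...) {
  cat("<titre_fit> endo ~ mt on ", x$n, " lines\n", sep = "")
  cat(sprintf("  slope %.4g, r %.4g, t %.3g, p %.3g\n",
              x$slope, x$correlation, x$statistic, x$p.value))
  invisible(x)
}

#' @export
tidy.titre_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "mt"),
    estimate = c(x$intercept, x$slope),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p.value)
  )
}

#' @export
glance.titre_fit <- function(x, ...) {
  tibble::tibble(r = x$correlation, r.squared = x$correlation^2,
                 statistic = x$statistic, p.value = x$p.value, nobs = x$n)
}
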