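#' Depth and breadth of coverage for one sample
#'
#' Depth of coverage is the mean read depth over every base of the
#' contig; breadth is the fraction of bases covered by at least
#' `min_reads` reads (two by default — a single stray read does not count
#' a base as covered).
#'
#' @param profile A [depth_profile()].
#' @param min_reads Minimum reads for a base to count as covered
#'   (default 2).
#' @return One-row tibble: `sample`, `contig`, `mean_depth`, `breadth`.
#' @export
coverage_summary <- function(profile, min_reads = 2L) {
  d <- profile$depth
  tibble::tibble(
    sample = profile$sample,
    contig = profile$contig,
    mean_depth = mean(d),
    breadth = mean(d >= min_reads)
  )
}

#' Classify infection status from coverage
#'
#' A line is scored infected when breadth strictly exceeds `min_breadth`
#' AND mean depth strictly exceeds `min_depth`. The defaults (90% breadth,
#' depth 1) suit panels with a clearly bimodal breadth distribution;
#' [breadth_gap()] reports how bimodal a panel actually is so threshold
#' overrides can be justified.
#'
#' @param summary Coverage tibble from [coverage_summary()] (any number of
#'   rows).
#' @param min_breadth Breadth threshold (default 0.90, strict).
#' @param min_depth Mean-depth threshold (default 1.0, strict).
#' @return `summary` with `status` (`"infected"`/`"uninfected"`) and a
#'   `rule` column recording the thresholds applied.
#' @export
classify_infection <- function(summary, min_breadth = 0.90, min_depth = 1.0) {
  stopifnot(min_breadth >= 0, min_breadth <= 1, min_depth >= 0)
  dplyr::mutate(
    summary,
    status = ifelse(.data$breadth > min_breadth & .data$mean_depth > min_depth,
                    "infected", "uninfected"),
    rule = sprintf("breadth>%g & mean_depth>%g", min_breadth, min_depth)
  )
}

#' Bimodality of a panel's breadth distribution
#'
#' Largest gap between consecutive sorted breadth values, with the gap's
#' location. A panel that splits cleanly into uninfected (breadth near 0)
#' and infected (breadth near 1) lines shows a large gap; a unimodal
#' panel does not, and fixed thresholds should then be questioned.
#'
#' @param breadths Numeric vector of per-sample breadths.
#' @return One-row tibble: `gap`, `below`, `above` (breadths flanking the
#'   largest gap).
#' @export
breadth_gap <- function(breadths) {
  b <- sort(breadths)
  if (length(b) < 2L)
    return(tibble::tibble(gap = 0, below = NA_real_, above = NA_real_))
  d <- diff(b)
  k <- which.max(d)
  tibble::tibble(gap = d[k], below = b[k], above = b[k + 1L])
}

#' Mask bases with anomalously high cross-sample coverage
#'
#' Bases whose mean depth across samples exceeds `factor` times the
#' contig-wide cross-sample mean are masked (merged into intervals).
#' Such regions — high in every sample — typically mark repeated
#' elements and are excluded from titre means.
#'
#' @param profiles List of [depth_profile()]s on a common contig.
#' @param factor Multiple of the contig-wide mean above which a base is
#'   masked (default 3).
#' @return Disjoint interval tibble ([genomic_intervals()]).
#' @export
mask_high_coverage <- function(profiles, factor = 3.0) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  contig <- unique(vapply(profiles, function(p) p$contig, ""))
  if (length(contig) > 1L)
    stop("profiles span several contigs", call. = FALSE)
  len <- unique(vapply(profiles, function(p) length(p$depth), 0L))
  if (length(len) > 1L) stop("profiles differ in length", call. = FALSE)
  cross_mean <- Reduce(`+`, lapply(profiles, function(p) as.numeric(p$depth))) /
    length(profiles)
  overall <- mean(cross_mean)
  if (overall == 0) stop("all-zero panel: contig-wide mean depth is 0",
                         call. = FALSE)
  if (!is.finite(factor)) return(genomic_intervals())
  high <- cross_mean > factor * overall
  runs_to_intervals(high, contig)
}

runs_to_intervals <- function(flag, contig) {
  if (!any(flag)) return(genomic_intervals())
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  genomic_intervals(contig, start[r$values], end[r$values])
}

#' Infection table for a panel
#'
#' @param profiles List of [depth_profile()]s (one per sample) on the
#'   target genome.
#' @param min_breadth,min_depth,min_reads Passed through to
#'   [coverage_summary()] and [classify_infection()].
#' @return Tibble: sample, contig, mean_depth, breadth, status, rule.
#' @export
infection_table <- function(profiles, min_breadth = 0.90, min_depth = 1.0,
                            min_reads = 2L) {
  purrr::map_dfr(profiles, coverage_summary, min_reads = min_reads) |>
    classify_infection(min_breadth = min_breadth, min_depth = min_depth)
}
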