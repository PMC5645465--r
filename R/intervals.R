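#' Genomic intervals as tibbles
#'
#' Intervals throughout the package are tibbles with columns `contig`,
#' `start`, `end`, using 1-based closed coordinates (the VCF convention).
#' BED files on disk use the usual 0-based half-open convention; the
#' readers/writers here convert between the two.
#'
#' @param contig,start,end Vectors of equal length (recycled scalars
#'   allowed).
#' @return A tibble with columns `contig`, `start`, `end`.
#' @export
genomic_intervals <- function(contig = character(), start = integer(),
                              end = integer()) {
  out <- tibble::tibble(contig = as.character(contig),
                        start = as.integer(start), end = as.integer(end))
  if (nrow(out) && any(out$start < 1L | out$end < out$start))
    stop("intervals need 1 <= start <= end", call. = FALSE)
  out
}

#' Merge overlapping or touching intervals
#'
#' @param intervals Interval tibble ([genomic_intervals()]).
#' @return Sorted, disjoint interval tibble (merge done per contig with
#'   [IRanges::reduce()]).
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(genomic_intervals())
  out <- intervals |>
    dplyr::group_by(.data$contig) |>
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$start)
  genomic_intervals(out$contig, out$start, out$end)
}

#' Logical mask over contig bases covered by intervals
#'
#' @param intervals Interval tibble restricted to one contig.
#' @param seq_length Contig length in bp.
#' @return Logical vector of length `seq_length`; `TRUE` inside intervals.
#' @export
interval_mask <- function(intervals, seq_length) {
  mask <- logical(seq_length)
  for (k in seq_len(nrow(intervals))) {
    mask[max(1L, intervals$start[k]):min(seq_length, intervals$end[k])] <- TRUE
  }
  mask
}

#' Read / write 3-column BED
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based
#' closed, so `start` gains 1 on read and loses 1 on write.
#'
#' @param path File path.
#' @return `read_bed()`: an interval tibble. `write_bed()`: `path`,
#'   invisibly.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = c("contig", "start", "end"),
                       col_types = "cii", comment = "#", progress = FALSE)
  genomic_intervals(d$contig, d$start + 1L, d$end)
}

#' @rdname read_bed
#' @param intervals Interval tibble.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(
    tibble::tibble(contig = intervals$contig, start = intervals$start - 1L,
                   end = intervals$end),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
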