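#' Per-base depth profile
#'
#' Dense per-base read depth for one sample on one contig — the unit of
#' input for infection calling and titre estimation.
#'
#' @param depth Non-negative integer vector, one entry per base.
#' @param sample Sample identifier.
#' @param contig Contig identifier.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(depth, sample, contig) {
  depth <- as.integer(round(depth))
  if (length(depth) == 0L) stop("depth vector must be non-empty", call. = FALSE)
  if (any(depth < 0L)) stop("depth entries must be >= 0", call. = FALSE)
  structure(list(sample = as.character(sample), contig = as.character(contig),
                 depth = depth),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> ", x$sample, " on ", x$contig, ": ",
      length(x$depth), " bp, mean depth ",
      sprintf("%.2f", mean(x$depth)), "\n", sep = "")
  invisible(x)
}

#' Read a bedtools-genomecov depth table
#'
#' Accepts both per-base output (`genomecov -d`: contig, 1-based position,
#' depth) and run-length output (`genomecov -bga`: contig, 0-based start,
#' end, depth). The dialect is auto-detected from the column count.
#' Positions absent from the table get depth 0.
#'
#' @param path Path to the TSV.
#' @param sample Sample identifier to attach.
#' @param contig Contig to extract (default: the single contig present).
#' @param seq_length Contig length; defaults to the largest coordinate
#'   seen.
#' @return A [depth_profile()].
#' @export
read_depth_table <- function(path, sample, contig = NULL, seq_length = NULL) {
  d <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       comment = "#", progress = FALSE)
  if (nrow(d) == 0L) {
    if (is.null(seq_length))
      stop("empty depth table and no seq_length given", call. = FALSE)
    return(depth_profile(integer(seq_length), sample,
                         contig %||% "unknown"))
  }
  if (!ncol(d) %in% c(3L, 4L))
    stop("depth table must have 3 (per-base) or 4 (run-length) columns",
         call. = FALSE)
  names(d) <- if (ncol(d) == 3L) c("contig", "pos", "depth")
              else c("contig", "start0", "end", "depth")
  if (is.null(contig)) {
    contig <- unique(d$contig)
    if (length(contig) > 1L)
      stop("depth table spans several contigs; pass `contig`", call. = FALSE)
  } else {
    d <- dplyr::filter(d, .data$contig == !!contig)
  }
  if (any(d$depth < 0)) stop("negative depth encountered", call. = FALSE)
  if (ncol(d) == 3L) {
    max_pos <- if (nrow(d)) max(d$pos) else 0L
    seq_length <- seq_length %||% max_pos
    if (max_pos > seq_length)
      stop("position ", max_pos, " exceeds contig length ", seq_length,
           call. = FALSE)
    depth <- integer(seq_length)
    depth[d$pos] <- as.integer(d$depth)
  } else {
    max_pos <- if (nrow(d)) max(d$end) else 0L
    seq_length <- seq_length %||% max_pos
    if (max_pos > seq_length)
      stop("interval end ", max_pos, " exceeds contig length ", seq_length,
           call. = FALSE)
    depth <- integer(seq_length)
    for (k in seq_len(nrow(d))) {
      if (d$end[k] > d$start0[k])
        depth[(d$start0[k] + 1L):d$end[k]] <- as.integer(d$depth[k])
    }
  }
  depth_profile(depth, sample, contig)
}

#' Write a depth profile as a genomecov-style table
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @param dialect `"d"` (per-base, 1-based) or `"bga"` (run-length,
#'   0-based half-open).
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path, dialect = c("d", "bga")) {
  dialect <- match.arg(dialect)
  if (dialect == "d") {
    out <- tibble::tibble(contig = profile$contig,
                          pos = seq_along(profile$depth),
                          depth = profile$depth)
  } else {
    r <- rle(profile$depth)
    end <- cumsum(r$lengths)
    out <- tibble::tibble(contig = profile$contig,
                          start0 = c(0L, end[-length(end)]),
                          end = end, depth = r$values)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Restrict a depth profile to an interval
#'
#' @param profile A [depth_profile()].
#' @param start,end 1-based closed bounds.
#' @return A [depth_profile()] over the sub-interval (contig annotated
#'   with the range).
#' @export
slice_profile <- function(profile, start, end) {
  if (start < 1L || end > length(profile$depth) || start > end)
    stop("interval outside profile", call. = FALSE)
  depth_profile(profile$depth[start:end], profile$sample,
                paste0(profile$contig, ":", start, "-", end))
}
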