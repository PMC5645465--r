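#' Retrieve the QC bookkeeping attached to a filtered object
#'
#' Every filter in the package attaches a tibble of per-rule removal
#' counts to its result; this accessor returns it (stacking reports from
#' chained filters).
#'
#' @param x An object returned by one of the `filter_*` / masking
#'   functions.
#' @return A tibble with columns `rule`, `removed`, `retained`.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    tibble::tibble(rule = character(), removed = integer(),
                   retained = integer())
}

add_report <- function(x, prev, rule, removed, retained) {
  rep_ <- dplyr::bind_rows(prev, tibble::tibble(
    rule = rule, removed = as.integer(removed),
    retained = as.integer(retained)))
  attr(x, "filter_report") <- rep_
  x
}

#' Keep only biallelic single-nucleotide records
#'
#' Drops indels (REF or any ALT longer than one base, or symbolic/`*`
#' alleles) and records with more than one ALT allele, the standard
#' pre-filter before any population statistic.
#'
#' @param records Record tibble from [read_vcf_records()] with `ref` and
#'   `alt` columns.
#' @return The retained records; removal counts via [filter_report()].
#' @export
filter_biallelic_snps <- function(records) {
  if (any(is.na(records$alt) | records$alt == ""))
    stop("malformed ALT field", call. = FALSE)
  n_alt <- stringr::str_count(records$alt, ",") + 1L
  multi <- n_alt > 1L
  alt1 <- records$alt
  is_indel <- !multi &
    (nchar(records$ref) != 1L | nchar(alt1) != 1L |
       !toupper(alt1) %in% c("A", "C", "G", "T"))
  keep <- !multi & !is_indel
  out <- records[keep, ]
  out <- add_report(out, filter_report(records), "indel", sum(is_indel),
                    nrow(records) - sum(is_indel))
  out <- add_report(out, filter_report(out), "non_biallelic", sum(multi),
                    sum(keep))
  attr(out, "contig_lengths") <- attr(records, "contig_lengths")
  out
}

#' Drop sites with too much missing data
#'
#' Sites whose missing fraction exceeds `max_missing` are removed — the
#' comparison is strict, so a site at exactly the threshold is kept.
#' Missingness is computed over the samples currently in the matrix, not
#' the original panel, so the filter is self-consistent on subsets.
#'
#' @param x A [variant_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @return Filtered [variant_matrix()]; counts via [filter_report()].
#' @export
filter_missingness <- function(x, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(x$alleles))
  keep <- miss <= max_missing
  out <- subset_sites(x, keep)
  add_report(out, filter_report(x), "missingness", sum(!keep), sum(keep))
}

#' Drop sites below a minor-allele count
#'
#' @param x A [variant_matrix()].
#' @param min_count Minimum copies of the minor allele (default 3,
#'   roughly a 2% frequency floor in a panel of 167 lines).
#' @return Filtered [variant_matrix()]; counts via [filter_report()].
#' @export
filter_minor_count <- function(x, min_count = 3L) {
  ss <- site_summary(x)
  keep <- ss$minor_count >= min_count
  out <- subset_sites(x, keep)
  add_report(out, filter_report(x), "minor_count", sum(!keep), sum(keep))
}

#' Mask regions of anomalously high SNP density
#'
#' Scans all placements of a `window_bp` sliding window and masks every
#' base lying in some placement that contains more than `max_snps`
#' variants; overlapping placements are merged. Such clusters (tens of
#' SNPs within 2 kb against a background of a few per 10 kb) typically
#' flag repeated elements rather than genuine polymorphism.
#'
#' @param positions Sorted variant coordinates (1-based).
#' @param contig Contig id for the output intervals.
#' @param seq_length Contig length (mask intervals are clipped to it).
#' @param window_bp Sliding-window width in bp (default 2000).
#' @param max_snps Variant count a window may contain before it is masked
#'   (default 20).
#' @return Merged, disjoint interval tibble ([genomic_intervals()]).
#' @export
mask_snp_dense_regions <- function(positions, contig, seq_length,
                                   window_bp = 2000L, max_snps = 20L) {
  if (window_bp <= 0L) stop("window_bp must be positive", call. = FALSE)
  positions <- sort(as.integer(positions))
  S <- length(positions)
  k <- as.integer(max_snps)
  if (S <= k) return(genomic_intervals())
  # window [s, s+w-1] holds > k variants iff it spans positions i..i+k for
  # some i, i.e. pos[i+k] - pos[i] <= w-1; the union of all such window
  # placements is [pos[i+k]-w+1, pos[i]+w-1]
  i <- seq_len(S - k)
  j <- i + k
  hit <- positions[j] - positions[i] <= window_bp - 1L
  if (!any(hit)) return(genomic_intervals())
  merge_intervals(genomic_intervals(
    contig,
    pmax(1L, positions[j][hit] - window_bp + 1L),
    pmin(as.integer(seq_length), positions[i][hit] + window_bp - 1L)
  ))
}

#' Drop variant-matrix sites inside masked intervals
#'
#' @param x A [variant_matrix()].
#' @param mask Interval tibble (same contig).
#' @return Filtered [variant_matrix()]; counts via [filter_report()].
#' @export
apply_site_mask <- function(x, mask) {
  mask <- mask[mask$contig == x$contig, ]
  inside <- rep(FALSE, n_sites(x))
  for (r in seq_len(nrow(mask))) {
    inside <- inside | (x$positions >= mask$start[r] &
                          x$positions <= mask$end[r])
  }
  out <- subset_sites(x, !inside)
  add_report(out, filter_report(x), "density_mask", sum(inside), sum(!inside))
}

#' Full site-level QC used by the pipeline
#'
#' Missingness filter followed by the SNP-density mask; the biallelic
#' filter has already run at VCF read time.
#'
#' @param x A [variant_matrix()].
#' @param max_missing Missingness ceiling (default 0.10).
#' @param window_bp,max_snps Density-mask parameters.
#' @return Filtered matrix; cumulative report via [filter_report()] and
#'   the density mask itself in the `density_mask` attribute.
#' @export
qc_matrix <- function(x, max_missing = 0.10, window_bp = 2000L,
                      max_snps = 20L) {
  x1 <- filter_missingness(x, max_missing)
  mask <- mask_snp_dense_regions(x1$positions, x1$contig, x1$seq_length,
                                 window_bp, max_snps)
  out <- apply_site_mask(x1, mask)
  attr(out, "density_mask") <- mask
  out
}
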