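#' Haploid-coded variant matrix
#'
#' The central container for panel genotypes on one contig: an
#' `n samples x S sites` integer matrix with entries `0` (reference allele),
#' `1` (alternate allele) or `NA` (missing / heterozygous-masked). Inbred
#' lines are haploid-coded: homozygous diploid calls collapse to a single
#' allele and heterozygous calls are treated according to a caller policy
#' (see [read_vcf_matrix()]).
#'
#' @param alleles Integer matrix (samples x sites) with entries in
#'   `{0, 1, NA}`. Row names, if present, are used as sample identifiers.
#' @param positions Integer vector of 1-based site coordinates, strictly
#'   increasing, one per column of `alleles`.
#' @param contig Contig (genome) identifier.
#' @param seq_length Total contig length in bp; used to normalise per-site
#'   statistics over monomorphic bases as well as variant sites.
#' @param ref,alt Optional character vectors of reference / alternate bases
#'   per site (required by [write_consensus_fasta()] and
#'   [write_matrix_vcf()]).
#' @param samples Sample identifiers; defaults to `rownames(alleles)` or
#'   `s1..sn`.
#'
#' @return An object of class `variant_matrix`.
#' @examples
#' m <- variant_matrix(
#'   rbind(a = c(0L, 1L), b = c(0L, NA), c = c(1L, 1L)),
#'   positions = c(10L, 40L), contig = "mt", seq_length = 100L
#' )
#' n_sites(m)
#' @export
variant_matrix <- function(alleles, positions, contig, seq_length,
                           ref = NULL, alt = NULL, samples = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  seq_length <- as.integer(seq_length)
  if (is.null(samples)) samples <- rownames(alleles)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(alleles)))
  rownames(alleles) <- samples
  colnames(alleles) <- NULL
  x <- structure(
    list(contig = as.character(contig), samples = samples,
         positions = positions, alleles = alleles,
         seq_length = seq_length, ref = ref, alt = alt),
    class = "variant_matrix"
  )
  validate_variant_matrix(x)
}

validate_variant_matrix <- function(x) {
  al <- x$alleles
  if (ncol(al) != length(x$positions))
    stop("number of allele columns must equal number of positions", call. = FALSE)
  if (nrow(al) != length(x$samples))
    stop("number of allele rows must equal number of samples", call. = FALSE)
  if (nrow(al) == 0L)
    stop("variant matrix must contain at least one sample", call. = FALSE)
  if (length(x$positions) > 0L) {
    if (any(diff(x$positions) <= 0L))
      stop("positions must be strictly increasing (duplicate or unsorted positions)",
           call. = FALSE)
    if (x$positions[1L] < 1L || x$positions[length(x$positions)] > x$seq_length)
      stop("positions must lie in [1, seq_length]", call. = FALSE)
    if (any(colSums(!is.na(al)) == 0L))
      stop("every site must have at least one non-missing call", call. = FALSE)
  }
  bad <- al[!is.na(al)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele entries must be 0, 1 or NA", call. = FALSE)
  for (fld in c("ref", "alt")) {
    if (!is.null(x[[fld]]) && length(x[[fld]]) != length(x$positions))
      stop(fld, " must have one entry per site", call. = FALSE)
  }
  x
}

#' @rdname variant_matrix
#' @param x A `variant_matrix`.
#' @export
n_samples <- function(x) nrow(x$alleles)

#' @rdname variant_matrix
#' @export
n_sites <- function(x) ncol(x$alleles)

#' @export
print.variant_matrix <- function(x, ...) {
  cat("<variant_matrix> contig ", x$contig, ": ", n_samples(x), " samples x ",
      n_sites(x), " sites (contig length ", x$seq_length, " bp)\n", sep = "")
  miss <- if (n_sites(x)) mean(is.na(x$alleles)) else 0
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.variant_matrix <- function(x, ...) {
  if (n_sites(x) == 0L) {
    return(tibble::tibble(contig = character(), sample = character(),
                          position = integer(), allele = integer()))
  }
  tibble::tibble(
    contig = x$contig,
    sample = rep(x$samples, times = n_sites(x)),
    position = rep(x$positions, each = n_samples(x)),
    allele = as.integer(x$alleles)
  )
}

#' Subset the sites of a variant matrix
#'
#' @param x A [variant_matrix()].
#' @param keep Logical or integer index over sites (columns).
#' @return A `variant_matrix` with the selected sites, order preserved.
#' @export
subset_sites <- function(x, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  variant_matrix(x$alleles[, idx, drop = FALSE], x$positions[idx],
                 x$contig, x$seq_length,
                 ref = x$ref[idx], alt = x$alt[idx], samples = x$samples)
}

#' Subset the samples of a variant matrix
#'
#' Sites losing all non-missing calls after subsetting are dropped (and
#' counted in the `dropped_sites` attribute) so the invariants still hold.
#'
#' @inheritParams subset_sites
#' @param samples Character vector of sample ids or index over rows.
#' @return A `variant_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  idx <- if (is.character(samples)) match(samples, x$samples) else as.integer(samples)
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  al <- x$alleles[idx, , drop = FALSE]
  ok <- colSums(!is.na(al)) > 0L
  out <- variant_matrix(al[, ok, drop = FALSE], x$positions[ok], x$contig,
                        x$seq_length, ref = x$ref[ok], alt = x$alt[ok],
                        samples = x$samples[idx])
  attr(out, "dropped_sites") <- sum(!ok)
  out
}

#' Per-site allele bookkeeping
#'
#' @param x A [variant_matrix()].
#' @return A tibble with one row per site: position, non-missing call count
#'   `m`, alternate-allele count `j`, minor-allele count and missing
#'   fraction.
#' @export
site_summary <- function(x) {
  al <- x$alleles
  m <- colSums(!is.na(al))
  j <- colSums(al == 1L, na.rm = TRUE)
  tibble::tibble(
    contig = x$contig,
    position = x$positions,
    m = as.integer(m),
    alt_count = as.integer(j),
    minor_count = as.integer(pmin(j, m - j)),
    missing_frac = 1 - m / n_samples(x)
  )
}
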