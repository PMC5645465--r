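#' Read a VCF into a tibble of variant records
#'
#' Thin wrapper over [vcfR::read.vcfR()] returning one row per record with
#' the fixed fields plus one genotype-string column per sample
#' (`gt_<sample>`). This is the record stream consumed by
#' [filter_biallelic_snps()] and [records_to_matrix()].
#'
#' @param path Path to a VCF (v4.x) file, plain or gzipped.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt` and one
#'   `gt_*` column per sample. Header contig lengths, if present, are kept
#'   in the `contig_lengths` attribute (named integer vector).
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  names(fix) <- tolower(names(fix))
  out <- tibble::tibble(
    chrom = fix$chrom,
    pos = as.integer(fix$pos),
    id = fix$id,
    ref = fix$ref,
    alt = fix$alt
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)
  if (nrow(out) > 0L) {
    gtw <- as.data.frame(gt, stringsAsFactors = FALSE, optional = TRUE)
    names(gtw) <- paste0("gt_", colnames(gt))
    out <- dplyr::bind_cols(out, tibble::as_tibble(gtw))
  } else {
    for (s in colnames(gt)) out[[paste0("gt_", s)]] <- character()
  }
  attr(out, "contig_lengths") <- vcf_contig_lengths(v)
  out
}

vcf_contig_lengths <- function(v) {
  meta <- v@meta
  ln <- meta[grepl("^##contig", meta)]
  if (!length(ln)) return(NULL)
  ids <- stringr::str_match(ln, "ID=([^,>]+)")[, 2]
  len <- suppressWarnings(as.integer(stringr::str_match(ln, "length=([0-9]+)")[, 2]))
  stats::setNames(len, ids)
}

#' Convert VCF records to a haploid-coded variant matrix
#'
#' Diploid genotypes from inbred lines collapse to haploid codes:
#' `0/0 -> 0`, `1/1 -> 1`, missing (`./.`) stays missing. Heterozygous
#' calls follow `het_policy`; the default codes them as missing, the
#' convention used when lines are expected to be fully inbred.
#'
#' @param records Record tibble from [read_vcf_records()] (possibly
#'   filtered).
#' @param contig Contig id; defaults to the single contig in `records`.
#' @param seq_length Contig length in bp; defaults to the VCF header value.
#' @param het_policy One of `"missing"`, `"ref"`, `"alt"`.
#' @return A [variant_matrix()].
#' @export
records_to_matrix <- function(records, contig = NULL, seq_length = NULL,
                              het_policy = c("missing", "ref", "alt")) {
  het_policy <- match.arg(het_policy)
  gt_cols <- grep("^gt_", names(records), value = TRUE)
  if (!length(gt_cols)) stop("records carry no genotype columns", call. = FALSE)
  if (is.null(contig)) {
    contig <- unique(records$chrom)
    if (length(contig) > 1L)
      stop("records span several contigs; pass `contig` explicitly", call. = FALSE)
    if (!length(contig)) contig <- "unknown"
  } else {
    records <- dplyr::filter(records, .data$chrom == contig)
  }
  if (is.null(seq_length)) {
    cl <- attr(records, "contig_lengths")
    seq_length <- cl[[contig]] %||% NA_integer_
    if (is.na(seq_length))
      stop("seq_length not given and absent from the VCF header", call. = FALSE)
  }
  if (anyDuplicated(records$pos))
    stop("duplicate positions on contig ", contig, call. = FALSE)
  ord <- order(records$pos)
  records <- records[ord, ]
  samples <- sub("^gt_", "", gt_cols)
  if (nrow(records) == 0L) {
    al <- matrix(integer(), nrow = 0L, ncol = length(samples),
                 dimnames = list(NULL, samples))
  } else {
    al <- vapply(gt_cols, function(cl) code_gt(records[[cl]], het_policy),
                 integer(nrow(records)))
    al <- matrix(as.integer(al), nrow = nrow(records),
                 dimnames = list(NULL, samples))
  }
  variant_matrix(t(al), positions = records$pos, contig = contig,
                 seq_length = seq_length, ref = records$ref,
                 alt = records$alt, samples = samples)
}

# GT string -> haploid code; handles "0","1","0/0","0|1","./." etc.
code_gt <- function(gt, het_policy) {
  a <- stringr::str_split_fixed(gt, "[/|]", 2)
  a1 <- a[, 1]
  a2 <- ifelse(a[, 2] == "", a[, 1], a[, 2])
  out <- rep(NA_integer_, length(gt))
  both01 <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  hom <- both01 & a1 == a2
  out[hom] <- as.integer(a1[hom])
  het <- both01 & a1 != a2
  out[het] <- switch(het_policy, missing = NA_integer_, ref = 0L, alt = 1L)
  out
}

#' Read a VCF straight into a variant matrix
#'
#' Convenience composition of [read_vcf_records()], the biallelic-SNP
#' filter and [records_to_matrix()].
#'
#' @inheritParams records_to_matrix
#' @param path Path to a VCF file.
#' @param biallelic_only Apply [filter_biallelic_snps()] first
#'   (default `TRUE`, the panel convention).
#' @return A [variant_matrix()]; the QC counts are in the
#'   `filter_report` attribute when `biallelic_only` is `TRUE`.
#' @export
read_vcf_matrix <- function(path, contig = NULL, seq_length = NULL,
                            het_policy = c("missing", "ref", "alt"),
                            biallelic_only = TRUE) {
  het_policy <- match.arg(het_policy)
  rec <- read_vcf_records(path)
  rep_ <- NULL
  if (biallelic_only) {
    rec <- filter_biallelic_snps(rec)
    rep_ <- filter_report(rec)
  }
  out <- records_to_matrix(rec, contig = contig, seq_length = seq_length,
                           het_policy = het_policy)
  attr(out, "filter_report") <- rep_
  out
}

#' Write a variant matrix as a minimal VCF v4.2 text file
#'
#' Haploid genotypes are written as single-allele GT fields (`0`, `1`,
#' `.`). `ref`/`alt` bases default to `A`/`T` placeholders when the matrix
#' does not carry them. Round-trips with [read_vcf_matrix()].
#'
#' @param x A [variant_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_matrix_vcf <- function(x, path) {
  ref <- x$ref %||% rep("A", n_sites(x))
  alt <- x$alt %||% rep("T", n_sites(x))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", x$contig, x$seq_length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- character(n_sites(x))
  for (s in seq_len(n_sites(x))) {
    gts <- x$alleles[, s]
    gts <- ifelse(is.na(gts), ".", as.character(gts))
    body[s] <- paste(c(x$contig, x$positions[s], ".", ref[s], alt[s], ".",
                       "PASS", ".", "GT", gts), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Build a per-sample consensus sequence from a variant matrix
#'
#' Substitutes the alternate base at every site where the sample carries
#' the alternate allele. Missing calls emit the reference base by default
#' (`missing_policy = "ref"`) or `N`.
#'
#' @param x A [variant_matrix()] carrying `ref`/`alt` bases.
#' @param reference Reference sequence as a single character string of
#'   length `x$seq_length`.
#' @param sample Sample identifier.
#' @param missing_policy `"ref"` or `"N"`.
#' @param file Optional path; when given the consensus is written as FASTA.
#' @return The consensus sequence (character scalar), invisibly when
#'   `file` is given.
#' @export
write_consensus_fasta <- function(x, reference, sample,
                                  missing_policy = c("ref", "N"),
                                  file = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (nchar(reference) != x$seq_length)
    stop("reference length (", nchar(reference), ") != seq_length (",
         x$seq_length, ")", call. = FALSE)
  if (n_sites(x) > 0L && is.null(x$alt))
    stop("matrix has no recorded alternate bases; cannot build consensus",
         call. = FALSE)
  i <- match(sample, x$samples)
  if (is.na(i)) stop("unknown sample: ", sample, call. = FALSE)
  bases <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (n_sites(x) > 0L) {
    g <- x$alleles[i, ]
    bases[x$positions[!is.na(g) & g == 1L]] <- x$alt[!is.na(g) & g == 1L]
    if (missing_policy == "N") bases[x$positions[is.na(g)]] <- "N"
  }
  seq <- paste(bases, collapse = "")
  if (!is.null(file)) {
    writeLines(c(paste0(">", sample), wrap_seq(seq)), file)
    return(invisible(seq))
  }
  seq
}

wrap_seq <- function(seq, width = 70L) {
  if (nchar(seq) == 0L) return(character())
  starts <- seq(1L, nchar(seq), by = width)
  substring(seq, starts, pmin(starts + width - 1L, nchar(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
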