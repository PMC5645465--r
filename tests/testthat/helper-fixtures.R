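# Fixtures are built in code at test time; nothing binary on disk.

# small VCF text writer for hand-constructed fixtures
write_toy_vcf <- function(path, records, samples = c("a", "b", "c"),
                          contig = "mt", len = 100L) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, len),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

toy_record <- function(pos, ref, alt, gts, contig = "mt") {
  paste(c(contig, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# random haploid matrix with optional missingness; every column kept
# polymorphic-ish and with >=1 call
rand_matrix <- function(n, S, miss = 0.1, seq_length = 10L * S + 10L) {
  al <- matrix(rbinom(n * S, 1L, runif(1, 0.1, 0.5)), nrow = n)
  if (miss > 0) al[matrix(runif(n * S) < miss, nrow = n)] <- NA_integer_
  keep <- colSums(!is.na(al)) > 0L
  al <- al[, keep, drop = FALSE]
  pos <- sort(sample.int(seq_length, ncol(al)))
  variant_matrix(al, pos, "sim", seq_length,
                 ref = rep("A", ncol(al)), alt = rep("T", ncol(al)))
}

# ---- independent brute-force oracles (explicit loops, no shared code) ----

brute_site_pi <- function(col) {
  col <- unname(col)
  idx <- which(!is.na(col))
  if (length(idx) < 2L) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in idx) for (j in idx) {
    if (i < j) { pairs <- pairs + 1; diffs <- diffs + (col[i] != col[j]) }
  }
  diffs / pairs
}

brute_Pi <- function(x) {
  tot <- 0
  for (s in seq_len(n_sites(x))) {
    v <- brute_site_pi(x$alleles[, s])
    if (!is.na(v)) tot <- tot + v
  }
  tot
}

brute_theta_w <- function(x) {
  n <- n_samples(x)
  a1 <- 0
  for (i in seq_len(n - 1)) a1 <- a1 + 1 / i
  n_sites(x) / (a1 * x$seq_length)
}

brute_tajimas_d <- function(x) {
  n <- n_samples(x); S <- n_sites(x)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (brute_Pi(x) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

brute_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

brute_hamming <- function(x) {
  n <- n_samples(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (s in seq_len(n_sites(x))) {
      a <- x$alleles[i, s]; b <- x$alleles[j, s]
      if (!is.na(a) && !is.na(b) && a != b) d[i, j] <- d[i, j] + 1
    }
  }
  d
}

# per-base sliding-window density scan: TRUE where some window with > k
# SNPs covers the base
brute_density_mask <- function(positions, seq_length, w, k) {
  masked <- logical(seq_length)
  for (s in seq_len(max(1L, seq_length - w + 1L))) {
    e <- s + w - 1L
    if (e > seq_length) break
    if (sum(positions >= s & positions <= e) > k) masked[s:e] <- TRUE
  }
  masked
}
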