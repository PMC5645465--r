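#' Linkage disequilibrium between two genomes
#'
#' For every pair of sites (one from each matrix) computes `r^2`, the
#' squared product-moment correlation of the two haploid 0/1 genotype
#' vectors over samples called at both sites. With strictly co-inherited
#' genomes (single maternal lineage, no recombination) shared-branch
#' variants give `r^2 = 1`; under free recombination the null expectation
#' of `r^2` is about `1/(n-1)`. Pairs whose vectors are constant after
#' pairwise deletion are undefined and counted separately.
#'
#' @param A,B [variant_matrix()] objects over the same samples in the
#'   same order.
#' @return Object of class `cross_ld`: tibble `pairs` (`pos_a`, `pos_b`,
#'   `n_complete`, `r2`), plus undefined-pair count.
#' @export
inter_genome_r2 <- function(A, B) {
  if (!identical(A$samples, B$samples))
    stop("A and B must cover the same samples in the same order",
         call. = FALSE)
  ga <- A$alleles
  gb <- B$alleles
  Sa <- n_sites(A); Sb <- n_sites(B)
  pairs <- tidyr::expand_grid(ia = seq_len(Sa), ib = seq_len(Sb))
  r2 <- numeric(nrow(pairs))
  ncomp <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- ga[, pairs$ia[k]]
    y <- gb[, pairs$ib[k]]
    ok <- !is.na(x) & !is.na(y)
    ncomp[k] <- sum(ok)
    r2[k] <- if (ncomp[k] < 2L || stats::var(x[ok]) == 0 ||
                   stats::var(y[ok]) == 0) NA_real_
             else stats::cor(x[ok], y[ok])^2
  }
  structure(list(
    pairs = tibble::tibble(pos_a = A$positions[pairs$ia],
                           pos_b = B$positions[pairs$ib],
                           n_complete = ncomp, r2 = r2),
    contig_a = A$contig, contig_b = B$contig,
    n_undefined = sum(is.na(r2))
  ), class = "cross_ld")
}

#' @export
print.cross_ld <- function(x, ...) {
  cat("<cross_ld> ", x$contig_a, " x ", x$contig_b, ": ",
      nrow(x$pairs), " pairs (", x$n_undefined, " undefined)\n", sep = "")
  s <- mean_r2(x)
  cat(sprintf("  mean r2 over defined pairs: %.4g\n", s))
  invisible(x)
}

#' Mean cross-genome r-squared
#'
#' @param x A [inter_genome_r2()] result.
#' @param undefined_as_zero Also average undefined pairs as 0 instead of
#'   excluding them (both summaries are reported by [tidy()] since the
#'   convention matters at this LD scale).
#' @return Mean r2 over defined pairs (default), or over all pairs with
#'   undefined treated as 0.
#' @export
mean_r2 <- function(x, undefined_as_zero = FALSE) {
  v <- x$pairs$r2
  if (all(is.na(v)))
    stop("no defined pairs: every pair is constant after pairwise deletion",
         call. = FALSE)
  if (undefined_as_zero) mean(ifelse(is.na(v), 0, v)) else mean(v, na.rm = TRUE)
}

#' @export
tidy.cross_ld <- function(x, ...) x$pairs

#' @export
glance.cross_ld <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_undefined = x$n_undefined,
    mean_r2 = mean_r2(x),
    mean_r2_undef_zero = mean_r2(x, undefined_as_zero = TRUE)
  )
}
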