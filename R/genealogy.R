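#' Pairwise difference (Hamming) matrix over jointly called sites
#'
#' `d(i, j)` counts sites where samples `i` and `j` are both called and
#' disagree; the companion overlap matrix counts jointly called sites,
#' so identity can be required to rest on enough shared data.
#'
#' @param x A [variant_matrix()] with n >= 2 samples.
#' @return Object of class `distance_matrix`: `d` (differences),
#'   `overlap` (joint call counts), `samples`.
#' @export
hamming_matrix <- function(x) {
  if (n_samples(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  al <- x$alleles
  called <- !is.na(al)
  one <- al == 1L & called
  zero <- al == 0L & called
  mode(one) <- "numeric"; mode(zero) <- "numeric"; mode(called) <- "numeric"
  d <- one %*% t(zero) + zero %*% t(one)
  ov <- called %*% t(called)
  dimnames(d) <- dimnames(ov) <- list(x$samples, x$samples)
  structure(list(d = round(d), overlap = round(ov), samples = x$samples,
                 n_sites = n_sites(x)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", length(x$samples), " samples over ",
      x$n_sites, " sites; mean pairwise differences ",
      sprintf("%.2f", mean(x$d[upper.tri(x$d)])), "\n", sep = "")
  invisible(x)
}

#' Count samples identical to at least one other sample
#'
#' A sample is non-unique when some other sample shows zero differences
#' over at least `min_overlap` jointly called sites. In a panel swept by
#' a single recent maternal lineage most sequences are identical, so
#' this count is large; deep neutral genealogies give near zero.
#'
#' @param dist A [hamming_matrix()] result.
#' @param min_overlap Minimum jointly called sites for identity to count
#'   (default: 80% of the matrix's sites, and at least 1).
#' @return Integer count of non-unique samples.
#' @export
count_nonunique <- function(dist, min_overlap = NULL) {
  min_overlap <- min_overlap %||% max(1, ceiling(0.8 * dist$n_sites))
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  identical_to <- dist$d == 0 & dist$overlap >= min_overlap
  diag(identical_to) <- FALSE
  sum(rowSums(identical_to) > 0L)
}

#' Neighbor-joining sketch of the panel genealogy
#'
#' Builds an NJ tree (via [ape::nj()]) from per-site normalised pairwise
#' differences and returns Newick text. Negative NJ branch lengths are
#' clipped to zero. This is a quick distance-based sketch for eyeballing
#' star-likeness, not a substitute for maximum-likelihood inference with
#' bootstrap support.
#'
#' @param dist A [hamming_matrix()] result (n >= 3).
#' @param file Optional path for the Newick text.
#' @return Newick string (invisibly when `file` is given); the `phylo`
#'   object is attached as attribute `tree`.
#' @export
nj_tree <- function(dist, file = NULL) {
  n <- length(dist$samples)
  if (n < 3L) stop("NJ needs at least 3 samples", call. = FALSE)
  if (all(dist$d == 0)) {
    # degenerate: every sequence identical -> explicit star topology
    nwk <- paste0("(", paste0(dist$samples, ":0", collapse = ","), ");")
    tree <- ape::read.tree(text = nwk)
  } else {
    ov <- pmax(dist$overlap, 1)
    tree <- ape::nj(stats::as.dist(dist$d / ov))
    tree$edge.length <- pmax(tree$edge.length, 0)
    nwk <- ape::write.tree(tree)
  }
  if (!is.null(file)) {
    writeLines(nwk, file)
    attr(nwk, "tree") <- tree
    return(invisible(nwk))
  }
  attr(nwk, "tree") <- tree
  nwk
}

#' Genealogy summary for one genome
#'
#' @param x A [variant_matrix()].
#' @param min_overlap Passed to [count_nonunique()].
#' @return One-row tibble: n, S, non-unique count and fraction, mean and
#'   max pairwise differences.
#' @export
genealogy_summary <- function(x, min_overlap = NULL) {
  dm <- hamming_matrix(x)
  nn <- count_nonunique(dm, min_overlap)
  ut <- dm$d[upper.tri(dm$d)]
  tibble::tibble(
    contig = x$contig, n = n_samples(x), S = n_sites(x),
    n_nonunique = nn, frac_nonunique = nn / n_samples(x),
    mean_pairwise_diff = mean(ut), max_pairwise_diff = max(ut)
  )
}
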