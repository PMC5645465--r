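# Neutral constant-size coalescent without recombination, conditioned on
# the number of segregating sites by sprinkling exactly S infinite-sites
# mutations on branches with probability proportional to branch length
# (Hudson's fixed-S device).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a neutral coalescent genealogy
#'
#' Kingman coalescent for `n` haploid lineages in a constant-size
#' population: with `k` lineages active the time to the next coalescence
#' is Exponential with rate `k (k - 1) / 2` (coalescent units), and the
#' coalescing pair is uniform. Expected total branch length is
#' `2 * a1(n)`.
#'
#' @param n Number of leaves (>= 2).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An object of class `coalescent_tree`: nodes `1..n` are leaves,
#'   `n+1..2n-1` internal in coalescence order, with fields `parent`
#'   (0 at the root), `time` (node ages), `length` (branch above each
#'   node) and `n_desc` (leaves below each node).
#' @export
simulate_genealogy <- function(n, seed = NULL) {
  if (n < 2L) stop("need n >= 2 lineages", call. = FALSE)
  with_seed(seed, {
    n_nodes <- 2L * n - 1L
    parent <- integer(n_nodes)
    time <- numeric(n_nodes)
    n_desc <- integer(n_nodes)
    n_desc[1:n] <- 1L
    active <- 1:n
    t <- 0
    for (nxt in (n + 1L):n_nodes) {
      k <- length(active)
      t <- t + stats::rexp(1L, k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      i <- active[pair[1L]]; j <- active[pair[2L]]
      parent[c(i, j)] <- nxt
      time[nxt] <- t
      n_desc[nxt] <- n_desc[i] + n_desc[j]
      active <- c(active[-pair], nxt)
    }
    len <- numeric(n_nodes)
    nz <- parent > 0L
    len[nz] <- time[parent[nz]] - time[nz]
    structure(list(n = n, parent = parent, time = time, length = len,
                   n_desc = n_desc),
              class = "coalescent_tree")
  })
}

#' @export
print.coalescent_tree <- function(x, ...) {
  cat("<coalescent_tree> ", x$n, " leaves, height ",
      sprintf("%.3f", max(x$time)), ", total length ",
      sprintf("%.3f", total_branch_length(x)), " (coalescent units)\n",
      sep = "")
  invisible(x)
}

#' Total branch length of a coalescent tree
#'
#' @param tree A `coalescent_tree`.
#' @return Sum of all branch lengths in coalescent units.
#' @export
total_branch_length <- function(tree) sum(tree$length)

#' Place a fixed number of mutations on a genealogy
#'
#' Drops exactly `S` infinite-sites mutations, each on a branch chosen
#' with probability proportional to its length; the resulting site's
#' derived allele is carried by every leaf below that branch, so derived
#' counts always lie in `1..n-1` and the matrix has exactly `S`
#' polymorphic columns.
#'
#' @param tree A [simulate_genealogy()] result.
#' @param S Number of segregating sites (>= 1).
#' @param seq_length Contig length for the output matrix; defaults to
#'   `S` (unit grid). Must be >= `S`.
#' @param contig Contig id for the output matrix.
#' @param seed Optional seed.
#' @return A [variant_matrix()] with `S` columns.
#' @export
sprinkle_fixed_s <- function(tree, S, seq_length = NULL, contig = "sim",
                             seed = NULL) {
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  seq_length <- as.integer(seq_length %||% S)
  if (seq_length < S) stop("seq_length must be >= S", call. = FALSE)
  with_seed(seed, {
    branch <- sample.int(length(tree$length), S, replace = TRUE,
                         prob = tree$length)
    kids <- split(seq_along(tree$parent), tree$parent)
    leaves_below <- function(v) {
      stack <- v; out <- integer(0)
      while (length(stack)) {
        u <- stack[[1L]]; stack <- stack[-1L]
        if (u <= tree$n) out <- c(out, u)
        else stack <- c(stack, kids[[as.character(u)]])
      }
      out
    }
    al <- matrix(0L, nrow = tree$n, ncol = S)
    for (s in seq_len(S)) al[leaves_below(branch[s]), s] <- 1L
    pos <- sort(sample.int(seq_length, S))
    base_pairs <- matrix(c("A", "C", "A", "G", "A", "T", "C", "T",
                           "G", "C", "T", "G"), ncol = 2, byrow = TRUE)
    bp <- base_pairs[sample.int(nrow(base_pairs), S, replace = TRUE), ,
                     drop = FALSE]
    variant_matrix(al, pos, contig, seq_length, ref = bp[, 1], alt = bp[, 2])
  })
}

# fast replicate: branch lengths + descendant counts only (no topology
# bookkeeping); O(n) memory, used by null_distribution
sim_branch_spectrum <- function(n) {
  n_nodes <- 2L * n - 1L
  birth <- numeric(n_nodes)
  desc <- integer(n_nodes)
  desc[1:n] <- 1L
  blen <- numeric(n_nodes - 1L)
  bdesc <- integer(n_nodes - 1L)
  active <- 1:n
  t <- 0
  bi <- 1L
  for (nxt in (n + 1L):n_nodes) {
    k <- length(active)
    t <- t + stats::rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    i <- active[pair[1L]]; j <- active[pair[2L]]
    blen[bi] <- t - birth[i]; bdesc[bi] <- desc[i]
    blen[bi + 1L] <- t - birth[j]; bdesc[bi + 1L] <- desc[j]
    bi <- bi + 2L
    birth[nxt] <- t
    desc[nxt] <- desc[i] + desc[j]
    active <- c(active[-pair], nxt)
  }
  list(len = blen, desc = bdesc)
}

#' Null distribution of a statistic under the fixed-S coalescent
#'
#' Draws `R` independent replicates of (genealogy, S sprinkled
#' mutations, statistic). Statistics: `"D"` (Tajima's D) or `"pi"`
#' (per-locus mean pairwise difference). Because `S >= 1` is fixed,
#' every replicate is defined.
#'
#' @param n Sample size (>= 4 for D, >= 2 for pi).
#' @param S Segregating sites to condition on (>= 1).
#' @param R Number of replicates (default 10000).
#' @param statistic `"D"` or `"pi"`.
#' @param seed Optional seed, recorded in the result.
#' @return Object of class `null_distribution`: `values` (length `R`),
#'   plus `statistic`, `n`, `S`, `R`, `seed`.
#' @export
null_distribution <- function(n, S, R = 10000L, statistic = c("D", "pi"),
                              seed = NULL) {
  statistic <- match.arg(statistic)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  if (statistic == "D" && n < 4L) stop("D needs n >= 4", call. = FALSE)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  cst <- if (statistic == "D") tajima_constants(n) else NULL
  values <- with_seed(seed, vapply(seq_len(R), function(r) {
    br <- sim_branch_spectrum(n)
    j <- br$desc[sample.int(length(br$len), S, replace = TRUE,
                            prob = br$len)]
    Pi <- sum(2 * j * (n - j) / (n * (n - 1)))
    if (statistic == "pi") Pi
    else (Pi - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }, numeric(1)))
  structure(list(statistic = statistic, values = values, n = n, S = S,
                 R = as.integer(R), seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$statistic, " | n = ", x$n, ", S = ", x$S,
      ", R = ", x$R, "\n", sep = "")
  cat(sprintf("  mean %.4g, sd %.4g, 95%% CI (%.4g, %.4g)\n",
              mean(x$values), stats::sd(x$values),
              null_ci(x)$low, null_ci(x)$high))
  invisible(x)
}

#' Empirical p-value against a simulated null
#'
#' Uses the add-one rule `p = (#{x <= obs} + 1) / (R + 1)` (lower tail;
#' upper symmetric; two-sided doubles the smaller tail, capped at 1) so
#' p can never be exactly zero.
#'
#' @param observed Observed statistic value.
#' @param null A [null_distribution()].
#' @param tail `"lower"`, `"upper"` or `"two-sided"`.
#' @return Empirical p-value.
#' @export
empirical_p <- function(observed, null,
                        tail = c("lower", "upper", "two-sided")) {
  tail <- match.arg(tail)
  v <- null$values
  R <- length(v)
  if (!R) stop("empty null distribution", call. = FALSE)
  lo <- (sum(v <= observed) + 1) / (R + 1)
  hi <- (sum(v >= observed) + 1) / (R + 1)
  switch(tail, lower = lo, upper = hi,
         `two-sided` = min(1, 2 * min(lo, hi)))
}

#' Confidence interval of a simulated null
#'
#' Empirical central interval from type-7 quantiles.
#'
#' @param null A [null_distribution()].
#' @param level Coverage (default 0.95).
#' @return One-row tibble with `low`, `high`.
#' @export
null_ci <- function(null, level = 0.95) {
  if (length(null$values) < 40L)
    warning("fewer than 40 replicates: interval is unstable", call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(null$values, c(a, 1 - a), names = FALSE, type = 7)
  tibble::tibble(low = q[1], high = q[2])
}

#' Test an observed statistic against the fixed-S coalescent null
#'
#' Convenience wrapper: simulate the null, compute the empirical p and
#' the 95% CI.
#'
#' @inheritParams null_distribution
#' @param observed Observed statistic value.
#' @param tail Tail for [empirical_p()]. There is no default in spirit:
#'   a sweep/bottleneck alternative implies `"lower"` for D.
#' @param level CI coverage.
#' @return Object of class `null_test` with [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
null_test <- function(observed, n, S, R = 10000L,
                      statistic = c("D", "pi"),
                      tail = c("lower", "upper", "two-sided"),
                      level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  null <- null_distribution(n, S, R, statistic, seed)
  ci <- null_ci(null, level)
  structure(list(observed = observed, null = null, tail = tail,
                 p.value = empirical_p(observed, null, tail),
                 ci = ci, level = level,
                 outside_ci = observed < ci$low | observed > ci$high),
            class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat("<null_test> observed ", x$null$statistic, " = ", x$observed,
      " vs fixed-S coalescent (n = ", x$null$n, ", S = ", x$null$S,
      ", R = ", x$null$R, ")\n", sep = "")
  cat(sprintf("  empirical p (%s) = %.4g; %g%% CI (%.4g, %.4g)%s\n",
              x$tail, x$p.value, 100 * x$level, x$ci$low, x$ci$high,
              if (x$outside_ci) " [observed outside CI]" else ""))
  invisible(x)
}

#' @export
tidy.null_test <- function(x, ...) {
  tibble::tibble(statistic = x$null$statistic, observed = x$observed,
                 null_mean = mean(x$null$values),
                 null_sd = stats::sd(x$null$values),
                 ci_low = x$ci$low, ci_high = x$ci$high,
                 tail = x$tail, p.value = x$p.value)
}

#' @export
glance.null_test <- function(x, ...) {
  tibble::tibble(n = x$null$n, S = x$null$S, R = x$null$R,
                 p.value = x$p.value, outside_ci = x$outside_ci)
}
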