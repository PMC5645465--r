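#' @importFrom ggplot2 ggplot aes geom_histogram geom_vline
#'   geom_point geom_smooth geom_line geom_hline labs facet_wrap
#'   theme_minimal
NULL

#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(value = object$values)
  ci <- null_ci(object)
  p <- ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = c(ci$low, ci$high), linetype = "dashed") +
    labs(x = paste0("null ", object$statistic,
                    "  (n = ", object$n, ", S = ", object$S,
                    ", R = ", object$R, ")"),
         y = "replicates",
         title = "Fixed-S coalescent null distribution") +
    theme_minimal()
  if (!is.null(observed))
    p <- p + geom_vline(xintercept = observed, colour = "firebrick",
                        linewidth = 1)
  p
}

#' @export
autoplot.null_test <- function(object, ...) {
  autoplot(object$null, observed = object$observed, ...) +
    labs(subtitle = sprintf("observed = %.3g, empirical %s-tail p = %.3g",
                            object$observed, object$tail, object$p.value))
}

#' @export
autoplot.titre_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mt, y = .data$endo)) +
    geom_point(alpha = 0.6) +
    geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                colour = "firebrick") +
    labs(x = "relative mtDNA copy number",
         y = "relative endosymbiont copy number",
         title = "mtDNA vs endosymbiont titre",
         subtitle = sprintf("r = %.3f, p = %.2g", object$correlation,
                            object$p.value)) +
    theme_minimal()
}

#' Windowed diversity track
#'
#' @param windowed Tibble from [windowed_stats()] (several contigs may
#'   be row-bound).
#' @return A ggplot: pi and Tajima's D per window, faceted by contig.
#' @export
plot_windowed_stats <- function(windowed) {
  long <- tidyr::pivot_longer(windowed, c("pi", "D"),
                              names_to = "statistic", values_to = "value")
  ggplot(long, aes(x = (.data$start + .data$end) / 2, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~ .data$contig + .data$statistic, scales = "free_y") +
    labs(x = "window midpoint (bp)", y = NULL,
         title = "Windowed nucleotide diversity and Tajima's D") +
    theme_minimal()
}

#' Association profile across candidate regions
#'
#' @param results Association tibble ([single_trait_assoc()] /
#'   [multivariate_assoc()] output, possibly row-bound).
#' @param alpha Cutoff drawn as a horizontal line (default 9e-6).
#' @return A ggplot of -log10 p against position, coloured by model.
#' @export
plot_association <- function(results, alpha = 9e-6) {
  ggplot(results, aes(x = .data$position, y = -log10(.data$p.value),
                      colour = .data$model)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    facet_wrap(~ .data$contig, scales = "free_x") +
    labs(x = "position (bp)", y = expression(-log[10](p)),
         title = "SNP-titre association") +
    theme_minimal()
}
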