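# Cosmetic plotting hooks. ggplot2 is only suggested; both functions
# error informatively when it is absent.

#' Plot a replication grid: p-value bands, power, and class-split effects
#'
#' Two stacked panels per true correlation: the central 90% and 50%
#' p-value bands with the median and the power curve above, and the
#' significant / non-significant effect-size bands with the true value
#' below.
#'
#' @param grid A `replication_grid` from [run_grid()].
#' @return A ggplot object.
#' @export
plot_replication <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  stopifnot(inherits(grid, "replication_grid"))
  df <- as.data.frame(grid)
  need <- c("p_q5", "p_q25", "p_q50", "p_q75", "p_q95",
            "r_sig_q5", "r_sig_q95", "r_nonsig_q5", "r_nonsig_q95")
  if (!all(need %in% names(df)))
    stop("plotting needs the default quantile bands (5/25/50/75/95)",
         call. = FALSE)
  pv <- cbind(df[c("rho", "n", "power")],
              df[grep("^p_q", names(df))], panel = "p-values and power")
  ef <- cbind(df[c("rho", "n")],
              df[grep("^r_(non)?sig_q", names(df))],
              panel = "effect-size estimates by class")
  p1 <- ggplot2::ggplot(pv, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p_q5,
                                         ymax = .data$p_q95),
                            colour = "lightblue", linewidth = 1.6) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p_q25,
                                         ymax = .data$p_q75),
                            colour = "steelblue", linewidth = 1.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_q50), shape = 95, size = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$power), colour = "darkblue",
                        size = 1) +
    ggplot2::geom_hline(yintercept = unique(df$alpha)[1]) +
    ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "p-value / power", x = "sample size n")
  p2 <- ggplot2::ggplot(ef, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$r_sig_q5,
                                         ymax = .data$r_sig_q95),
                            colour = "orange", linewidth = 1.2) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$r_nonsig_q5,
                                         ymax = .data$r_nonsig_q95),
                            colour = "purple", linewidth = 1.2,
                            position = ggplot2::position_nudge(x = 0.6)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$rho)) +
    ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "sample correlation r", x = "sample size n")
  if (requireNamespace("patchwork", quietly = TRUE))
    return(patchwork::wrap_plots(p1, p2, ncol = 1))
  p2
}

#' Plot a compatibility curve with its 95% interval bar
#'
#' @param curve A `compatibility_curve`.
#' @param level Interval level for the horizontal bar, default 0.95.
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  stopifnot(inherits(curve, "compatibility_curve"))
  iv <- interval_at_level(curve, level)
  df <- data.frame(rho = curve$grid, level = curve$levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::annotate("segment", x = iv$lower, xend = iv$upper,
                      y = 0, yend = 0, linewidth = 2) +
    ggplot2::geom_vline(xintercept = curve$point_estimate,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = range(curve$grid[curve$levels > 1e-4]),
                             ylim = c(0, 1)) +
    ggplot2::labs(x = "hypothesized true correlation",
                  y = "compatibility level (p-value)")
}
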