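#' Funnel plot of one microRNA's effect sizes
#'
#' Effect size against standard error (inverted axis, as is conventional),
#' with the fixed-effect centre and pseudo 95% confidence funnel.
#'
#' @param x A `mir_funnel` (from [funnel_data()]) or an effects tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_funnel <- function(x, ...) {
  if (!inherits(x, "mir_funnel")) x <- funnel_data(x)
  pts <- x$points
  se_max <- max(pts$se) * 1.05
  band <- tibble::tibble(
    se = seq(1e-6, se_max, length.out = 100),
    lo = x$center - z_quantile(0.95) * seq(1e-6, se_max, length.out = 100),
    hi = x$center + z_quantile(0.95) * seq(1e-6, se_max, length.out = 100)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$y, y = .data$se)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = NULL, xmin = .data$lo, xmax = .data$hi,
                                      y = .data$se),
                         inherit.aes = FALSE, fill = "grey85", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = x$center, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "standard error") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_funnel autoplot method for funnel data.
#' @export
autoplot.mir_funnel <- function(object, ...) plot_funnel(object, ...)

#' Forest-style plot of an analysis set
#'
#' Pooled REML log odds ratios with 95% confidence intervals, significant
#' microRNAs highlighted; restricted to the `n_max` smallest adjusted p
#' values to stay readable.
#'
#' @param object A `mir_analysis`.
#' @param n_max Maximum number of microRNAs shown (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_analysis <- function(object, n_max = 30, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$p_adj_reml) |>
    head(n_max) |>
    dplyr::mutate(mirna = factor(.data$mirna, levels = rev(.data$mirna)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mu_reml, y = .data$mirna,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey40")) +
    ggplot2::labs(x = "pooled log odds ratio (REML, 95% CI)", y = NULL,
                  colour = "significant",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Pathway impact overview plot
#'
#' Adjusted combined evidence per pathway on the -log10 scale.
#'
#' @param object A `mir_impact`.
#' @param alpha Reference significance level drawn as a line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_impact <- function(object, alpha = 0.05, ...) {
  dat <- tidy(object) |>
    dplyr::mutate(pathway_id = factor(.data$pathway_id,
                                      levels = rev(.data$pathway_id[order(.data$p_g_adj)])))
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(.data$p_g_adj), y = .data$pathway_id)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted" ~ p[G]), y = NULL) +
    ggplot2::theme_minimal()
}
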