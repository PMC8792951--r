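#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_tile
#'   geom_ribbon labs theme_minimal autoplot scale_fill_viridis_c facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot pan/core rarefaction curves
#'
#' Median pan and core sizes per genome count, optionally overlaid with the
#' fitted power-law / exponential curves.
#'
#' @param object A `rarefaction`.
#' @param fits Optional `pan_curve_fits` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction <- function(object, fits = NULL, ...) {
  med <- attr(object, "medians")
  df <- tidyr::pivot_longer(med, -x, names_to = "curve", values_to = "size")
  df$curve <- sub("_median", "", df$curve)
  p <- ggplot(df, aes(x = x, y = size, colour = curve)) +
    geom_point() + geom_line(linetype = 2) +
    labs(x = "genomes sampled", y = "gene families",
         colour = NULL, title = "Pan/core rarefaction") +
    theme_minimal()
  if (!is.null(fits)) {
    xx <- seq(min(med$x), max(med$x), length.out = 100)
    cfp <- fits$pan$coef; cfc <- fits$core$coef
    fit_df <- dplyr::bind_rows(
      tibble(x = xx, size = cfp[["a"]] * xx^cfp[["gamma"]] + cfp[["b"]],
             curve = "pan"),
      tibble(x = xx, size = cfc[["a"]] * exp(-cfc[["k"]] * xx) + cfc[["b"]],
             curve = "core"))
    p <- p + geom_line(data = fit_df)
  }
  p
}

#' Plot pan-genome category composition
#'
#' @param object A `pan_categories`.
#' @param ... Unused.
#' @return A ggplot bar chart of family counts per category.
#' @export
autoplot.pan_categories <- function(object, ...) {
  df <- dplyr::count(as_tibble(object), category)
  ggplot(df, aes(x = category, y = n, fill = category)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "gene families", title = "Pan-genome categories") +
    theme_minimal()
}

#' Heatmap of a pairwise genome metric
#'
#' @param object A `dist_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap.
#' @export
autoplot.dist_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = genome_a, y = genome_b, fill = value)) +
    geom_tile() + scale_fill_viridis_c(name = attr(object, "metric")) +
    labs(x = NULL, y = NULL) + theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-branch likely gain/loss events
#'
#' @param object An `event_profile`.
#' @param ... Unused.
#' @return A ggplot with gains and losses per branch, terminal branches
#'   distinguished.
#' @export
autoplot.event_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("likely_gains", "likely_losses"),
                        names_to = "event", values_to = "n")
  df$event <- sub("likely_", "", df$event)
  ggplot(df, aes(x = branch, y = n, fill = is_terminal)) +
    geom_col() + facet_wrap(~event, ncol = 1) +
    labs(x = "branch (child node)", y = "likely events",
         fill = "terminal") + theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
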