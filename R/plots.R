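# ggplot2 displays for the main result types.

#' @export
autoplot.interaction_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$species, levels = colnames(object)),
    y = factor(.data$hollow, levels = rev(rownames(object))),
    fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(
      x = "beetle species", y = "tree hollow", fill = "individuals",
      title = paste(c(attr(object, "site"), attr(object, "year")), collapse = " ")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.null_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red3",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "null draws",
      title = sprintf("%s: observed %.2f, p = %.3f",
                      object$statistic, object$observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.extinction_result <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$removed_frac, y = .data$surviving_frac, colour = .data$order
  )) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "fraction of hollows removed",
      y = "fraction of beetle species surviving",
      colour = "removal order"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.core_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$gc, y = .data$strength,
    colour = .data$strength_tier, shape = .data$qualitative_core
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 4, linetype = "dotted") +
    ggplot2::labs(
      x = "generalist-core score Gc", y = "species strength",
      colour = "strength tier", shape = "Gc core"
    ) +
    ggplot2::theme_minimal()
}

#' Compare extinction curves across networks
#'
#' Convenience plot for the per-site robustness comparison: one panel per
#' site, curves coloured by year or scenario.
#'
#' @param curves A tibble of curve points with columns `removed_frac`,
#'   `surviving_frac`, `order`, and grouping columns `site`, `label`.
#' @return A ggplot object.
#' @export
plot_extinction_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$removed_frac, y = .data$surviving_frac,
    colour = .data$label, linetype = .data$order
  )) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~site) +
    ggplot2::labs(
      x = "fraction of hollows removed",
      y = "fraction of beetle species surviving"
    ) +
    ggplot2::theme_minimal()
}
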