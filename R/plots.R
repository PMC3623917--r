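#' Mean correlation versus time scale
#'
#' The headline curve: ensemble-average Pearson correlation between the
#' protein self energy and the protein-water interaction energy as a
#' function of the (log10) time scale, one line per window exponent.
#'
#' @param report A `roughness_report`.
#' @return A ggplot object.
#' @export
plot_correlation <- function(report) {
  df <- tidy(report)
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$tau), y = .data$mean_r,
    colour = factor(.data$m), group = factor(.data$m)
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "log10 time scale", y = "mean Pearson r",
      colour = "m (n = 2^m)",
      title = "Protein / protein-water energy correlation across time scales"
    ) +
    ggplot2::theme_minimal()
}

#' Mean roughness versus time scale
#'
#' Mean population standard deviation of the protein self energy, the
#' protein-water interaction energy and their sum — the roughness of the
#' corresponding potential-energy surfaces — per time scale.
#'
#' @param report A `roughness_report`.
#' @param m Window exponent to show; defaults to the largest in the report.
#' @return A ggplot object.
#' @export
plot_roughness <- function(report, m = max(report$summaries$m)) {
  df <- tidy(report) |>
    filter(.data$m == !!m) |>
    tidyr::pivot_longer(
      c("mean_sigma_p", "mean_sigma_pw", "mean_sigma_tot"),
      names_to = "component", values_to = "sigma"
    ) |>
    mutate(component = factor(
      .data$component,
      levels = c("mean_sigma_p", "mean_sigma_pw", "mean_sigma_tot"),
      labels = c("sigma(E_p)", "sigma(E_p-w)", "sigma(E_tot)")
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$tau), y = .data$sigma,
    colour = .data$component, shape = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "log10 time scale", y = "mean sigma (kcal/mol)",
      title = sprintf("Energy-landscape roughness across time scales (m = %d)", m)
    ) +
    ggplot2::theme_minimal()
}

#' Roughening and smoothing probabilities versus time scale
#'
#' Per scale, the probability that the total-energy roughness is at least
#' the protein self-energy roughness (water roughens, `p_rough`) against
#' its complement (water smooths, `p_smooth`).
#'
#' @param report A `roughness_report`.
#' @param m Window exponent to show; defaults to the largest in the report.
#' @return A ggplot object.
#' @export
plot_probabilities <- function(report, m = max(report$summaries$m)) {
  df <- tidy(report) |>
    filter(.data$m == !!m) |>
    tidyr::pivot_longer(c("p_rough", "p_smooth"),
                        names_to = "effect", values_to = "probability") |>
    mutate(effect = factor(.data$effect, levels = c("p_rough", "p_smooth"),
                           labels = c("roughening", "smoothing")))
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$tau), y = .data$probability, fill = .data$effect
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "log10 time scale", y = "probability",
      title = sprintf("Net effect of water on landscape roughness (m = %d)", m)
    ) +
    ggplot2::theme_minimal()
}

#' Quadrant scatter of per-window statistics
#'
#' Each window on the `(delta_sigma, r)` plane, faceted by time scale.
#' Quadrant III (lower left) is where water smooths the protein's
#' landscape; I and IV are roughening; II (upper left) is algebraically
#' impossible and must stay empty.
#'
#' @param report A `roughness_report` built with `keep_windows = TRUE`.
#' @param m Window exponent to show; defaults to the largest in the report.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(report, m = max(report$summaries$m)) {
  mkey <- sprintf("m%d", m)
  if (length(report$windows[[mkey]]) == 0L) {
    stop_validation("report was built without per-window statistics (keep_windows = FALSE).")
  }
  df <- bind_rows(report$windows[[mkey]], .id = "scale") |>
    filter(!is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_sigma, y = .data$r,
                                   colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~scale, scales = "free_x") +
    ggplot2::labs(
      x = "delta sigma = sigma(E_tot) - sigma(E_p)  (kcal/mol)",
      y = "Pearson r",
      title = sprintf("Smoothing (III) vs roughening (I, IV) windows (m = %d)", m)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a roughness report
#'
#' @param object A `roughness_report`.
#' @param type One of `"correlation"`, `"roughness"`, `"probabilities"`,
#'   `"quadrants"`.
#' @param ... Passed to the specific `plot_*()` function.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.roughness_report <- function(object,
                                      type = c("correlation", "roughness",
                                               "probabilities", "quadrants"),
                                      ...) {
  type <- match.arg(type)
  switch(type,
    correlation = plot_correlation(object, ...),
    roughness = plot_roughness(object, ...),
    probabilities = plot_probabilities(object, ...),
    quadrants = plot_quadrants(object, ...)
  )
}

#' @export
ggplot2::autoplot
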