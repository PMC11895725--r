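#' Plot one or more Kaplan-Meier curves
#'
#' Step-function survival plot for `km_curve` objects, e.g. time to fill or
#' time to follow-up by fill status.
#'
#' @param curves A single `km_curve` or a named list of them (names become
#'   the legend).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_km <- function(curves, xlab = "Days", ylab = "Survival probability") {
  if (inherits(curves, "km_curve")) curves <- list(curve = curves)
  df <- purrr::imap_dfr(curves, function(curve, name) {
    as_tibble(curve) |> mutate(group = name)
  })
  # prepend S(0) = 1 so every step starts at the origin
  df <- bind_rows(
    df |> distinct(.data$group) |>
      mutate(time = 0, survival = 1, n_risk = NA_real_, n_event = NA_real_),
    df
  ) |> arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}
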