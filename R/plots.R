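#' Plot a microspecies profile
#'
#' Fraction of each protonation microstate across the pH grid.
#'
#' @param object A [microspecies_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nanosar_microspecies <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pH, y = .data$fraction,
                                       colour = .data$microspecies)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "microspecies fraction") +
    ggplot2::theme_minimal()
}

#' Plot a polar-group distance distribution
#'
#' Density of polar-group COM to nanotube-surface distances on
#' \[0, r_max\], with the 4 Angstrom AUC cutoff marked.
#'
#' @param object A `distance_distribution`.
#' @param cutoff Vertical reference line (Angstrom); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_distribution <- function(object, cutoff = 4, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey40") +
    ggplot2::labs(x = "surface distance (Å)",
                  y = "probability density (1/Å)") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = 2)
  }
  p
}

#' Plot a contact series
#'
#' Per-molecule contact-area traces over time, with the binding-event
#' threshold marked.
#'
#' @param object A [contact_series()] result.
#' @param threshold Horizontal reference (Angstrom^2, default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_series <- function(object, threshold = 30, ...) {
  dt <- attr(object, "dt") %||% 1
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frame * dt, y = .data$area)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~molecule, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (ns)", y = "contact area (Å²)") +
    ggplot2::theme_minimal()
}

#' Plot screening responses by category
#'
#' Dopamine-normalized responses in descending order, colored by response
#' category.
#'
#' @param responses A [screen_plate()] result.
#' @return A ggplot.
#' @export
plot_responses <- function(responses) {
  check_columns(responses, c("analyte_id", "normalized", "category"),
                "responses")
  df <- arrange(responses, dplyr::desc(.data$normalized))
  df$analyte_id <- factor(df$analyte_id, levels = df$analyte_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analyte_id,
                                   y = .data$normalized,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.10, 0.15, 0.50, 0.75, 1.00),
                        linetype = 3, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "normalized ΔF/F (DA = 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
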