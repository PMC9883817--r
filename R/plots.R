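#' Plot a scored cohort on the stress-by-rating plane
#'
#' Scatter of companies at (z_rating, z_stress), coloured by stress type
#' and sized by association `f`; the axes split the plane into the four
#' quadrants and the dotted lines mark the quadrant diagonals along which
#' association is maximal.
#'
#' @param object A `stress_quadrants` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_quadrants
#' @export
autoplot.stress_quadrants <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$z_rating, y = .data$z_stress,
                 colour = .data$stress_type, size = .data$f)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = c(1, -1), intercept = 0,
                         linetype = "dotted", colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::labs(
      x = "z(rating)", y = "z(stress score)",
      colour = "stress type", size = "association f",
      title = "Stress-by-rating quadrant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the yearly stress index
#'
#' One line per stress type over the scored years, with a ribbon of plus
#' or minus one dispersion (the across-company spread of contributions)
#' around each line.
#'
#' @param object A [yearly_stress_index()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot yearly_stress_index
#' @export
autoplot.yearly_stress_index <- function(object, ...) {
  dat <- filter(as_tibble(object), !is.na(.data$m))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$year, y = .data$m, colour = .data$stress_type,
                 fill = .data$stress_type)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$m - dplyr::coalesce(.data$dispersion, 0), 0),
        ymax = .data$m + dplyr::coalesce(.data$dispersion, 0)
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "year", y = "stress index m(s, y)",
      colour = "stress type", fill = "stress type",
      title = "Yearly stress index by type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot growth summaries
#'
#' Geometric-mean growth per percentile bin, one panel per stress type,
#' with error bars of plus or minus one geometric standard error; the
#' dashed line marks the type's pooled (overall) GM.
#'
#' @param object A `growth_summary` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot growth_summary
#' @export
autoplot.growth_summary <- function(object, ...) {
  dat <- as_tibble(object)
  bins <- filter(dat, .data$percentile_bin != "overall") %>%
    mutate(percentile_bin = as.integer(.data$percentile_bin))
  overall <- filter(dat, .data$percentile_bin == "overall")
  ggplot2::ggplot(
    bins,
    ggplot2::aes(x = .data$percentile_bin, y = .data$gm,
                 colour = .data$stress_type)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gm - dplyr::coalesce(.data$gse, 0),
                   ymax = .data$gm + dplyr::coalesce(.data$gse, 0)),
      width = 0.2
    ) +
    ggplot2::geom_hline(
      data = overall,
      ggplot2::aes(yintercept = .data$gm, colour = .data$stress_type),
      linetype = "dashed", alpha = 0.6
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stress_type)) +
    ggplot2::labs(
      x = "association percentile bin", y = "geometric mean growth",
      title = "Stock growth by stress type and percentile"
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
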