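#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth-dose curve
#'
#' @param object A [depth_dose()] curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_dose <- function(object, ...) {
  m <- curve_meta(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Depth (cm)",
                  y = if (m$normalization == "relative_max100")
                    "Dose (% of max)" else "Dose (abs.)",
                  title = sprintf("%s MeV %s, %g x %g cm", format(m$energy),
                                  m$foil, m$field_size, m$field_size)) +
    ggplot2::theme_minimal()
}

#' Plot a lateral profile
#'
#' @param object A [lateral_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lateral_profile <- function(object, ...) {
  m <- curve_meta(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Off-axis position (cm)", y = "Dose",
                  title = sprintf("Profile at %g cm depth", m$depth)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-volume histogram
#'
#' @param object A [dvh()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose, y = .data$volume_fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume fraction") +
    ggplot2::theme_minimal()
}

#' DVH plot of a scanned plan
#'
#' Cumulative DVHs of the target shell and the body structure.
#'
#' @param object An `sff_plan`.
#' @param bin_width DVH bin width in Gy.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sff_plan <- function(object, bin_width = 0.05, ...) {
  dd <- dplyr::bind_rows(
    dplyr::mutate(dvh(object$dose, object$phantom$masks$target, bin_width),
                  structure = "target"),
    dplyr::mutate(dvh(object$dose, object$phantom$masks$body, bin_width),
                  structure = "body"))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$dose,
                                   y = .data$volume_fraction,
                                   colour = .data$structure)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0.95 * object$rx, linetype = 2) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a scanning-resolution sweep
#'
#' CI, HI and normalized body mean dose against the swept resolution, one
#' facet per phantom, coloured by field size.
#'
#' @param sweep A [run_resolution_sweep()] table.
#' @param direction `"angular"` or `"longitudinal"`.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, direction = c("angular", "longitudinal")) {
  direction <- match.arg(direction)
  rows <- dplyr::filter(sweep, .data$sweep == direction, is.na(.data$error))
  rows$resolution <- if (direction == "angular") rows$dtheta else rows$dz
  long <- tidyr::pivot_longer(
    rows, c("ci", "hi", "normalized_body_mean"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resolution, y = .data$value,
                                     colour = factor(.data$field_size),
                                     shape = .data$metric)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~ kind + radius, scales = "free_y") +
    ggplot2::labs(x = if (direction == "angular")
      "Scanning angle resolution (deg)" else "Longitudinal resolution (cm)",
      y = NULL, colour = "Field (cm)", shape = NULL) +
    ggplot2::theme_minimal()
}
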