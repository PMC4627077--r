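#' Plot an ensemble fluorescence trace
#'
#' @param object An `ensemble_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_trace
#' @export
autoplot.ensemble_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$fluorescence_au)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = attr(object, "channel")) +
    ggplot2::theme_minimal()
}

#' Plot a species trajectory
#'
#' @param object A `species_trajectory`.
#' @param ... Unused.
#' @return A ggplot with one line per species.
#' @method autoplot species_trajectory
#' @export
autoplot.species_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "species", values_to = "conc_uM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$conc_uM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a single-molecule trace
#'
#' Donor/acceptor intensities with the FRET ratio in a lower panel, the
#' standard two-panel representation of a camera-frame smFRET recording.
#'
#' @param object An `sm_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sm_trace
#' @export
autoplot.sm_trace <- function(object, ...) {
  d <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(d, c("I_cy3", "I_cy5", "fret"),
                              names_to = "channel", values_to = "value")
  long$panel <- ifelse(long$channel == "fret", "FRET", "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(I_cy3 = "darkgreen",
                                            I_cy5 = "red", fret = "black")) +
    ggplot2::labs(x = "time from injection (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a postsynchronized FRET probability density
#'
#' @param object A `fret_density` from [density_plot()].
#' @param ... Unused.
#' @return A ggplot heat map (FRET vs time from the synchronization point).
#' @method autoplot fret_density
#' @export
autoplot.fret_density <- function(object, ...) {
  mids <- (object$fret_breaks[-1] + object$fret_breaks[-length(object$fret_breaks)]) / 2
  d <- expand.grid(fret = mids, time_s = object$time_s)
  d$density <- as.vector(object$density)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$fret,
                                  fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("time from %s of FRET event (s)",
                              sub("_", " ", object$sync)),
                  y = "FRET") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time survival curve and its exponential fit
#'
#' @param object A `dwell_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dwell_fit
#' @export
autoplot.dwell_fit <- function(object, ...) {
  if (is.null(object$survival)) stop("dwell_fit carries no survival curve", call. = FALSE)
  s <- object$survival
  s$fit <- object$amplitude * exp(-s$t / object$t_dissoc)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$S), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "survival fraction",
                  subtitle = sprintf("t_dissoc = %.3g s, k_dissoc = %.3g 1/s",
                                     object$t_dissoc, object$k_dissoc)) +
    ggplot2::theme_minimal()
}

#' Plot apparent rates versus concentration
#'
#' @param data Tibble with columns `concentration`, `rate` and optionally
#'   `channel`.
#' @param mm_fit Optional [fit_michaelis_menten()] result drawn as a curve.
#' @return A ggplot.
#' @export
plot_rate_concentration <- function(data, mm_fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$concentration,
                                          y = .data$rate)) +
    ggplot2::labs(x = "concentration (uM)", y = "apparent rate (1/s)") +
    ggplot2::theme_minimal()
  p <- if ("channel" %in% names(data))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$channel))
  else p + ggplot2::geom_point()
  if (!is.null(mm_fit)) {
    S <- seq(0, max(data$concentration) * 1.05, length.out = 100)
    curve <- tibble::tibble(concentration = S,
                            rate = mm_fit$Vmax * S / (mm_fit$KM + S))
    p <- p + ggplot2::geom_line(data = curve)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
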