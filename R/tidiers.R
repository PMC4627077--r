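#' Tidy methods for tufret fit objects
#'
#' Broom-style one-row-per-parameter summaries.
#'
#' @param x A fit object.
#' @param ... Unused.
#' @return A tibble.
#' @name tufret-tidiers
NULL

#' @rdname tufret-tidiers
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  if (x$model == "mono")
    tibble::tibble(term = c("F0", "F1", "k_prime"),
                   estimate = c(x$F0, x$F1, x$k_prime))
  else
    tibble::tibble(term = c("F0", "F1", "F2", "k1app", "k2app"),
                   estimate = c(x$F0, x$F1, x$F2, x$k1app, x$k2app))
}

#' @rdname tufret-tidiers
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, converged = x$converged,
                 degenerate = x$degenerate)
}

#' @rdname tufret-tidiers
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("Vmax", "KM"),
                 estimate = c(x$Vmax, x$KM),
                 std.error = c(x$Vmax_se, x$KM_se))
}

#' @rdname tufret-tidiers
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = sum(x$residuals^2), converged = x$converged,
                 degenerate = x$degenerate)
}

#' @rdname tufret-tidiers
#' @method tidy conc_fit
#' @export
tidy.conc_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @rdname tufret-tidiers
#' @method glance conc_fit
#' @export
glance.conc_fit <- function(x, ...) {
  tibble::tibble(rss = sum(x$residuals^2), n = length(x$residuals))
}

#' @rdname tufret-tidiers
#' @method tidy global_fit
#' @export
tidy.global_fit <- function(x, ...) {
  nms <- c("k12", "k_m12", "k3", "k4", "k4A", "k_m4A")
  nms <- nms[nms %in% c(x$free, names(x$fixed))]
  tibble::tibble(
    term = nms,
    estimate = vapply(nms, function(nm) x$rates[[nm]], numeric(1)),
    fixed = nms %in% names(x$fixed))
}

#' @rdname tufret-tidiers
#' @method glance global_fit
#' @export
glance.global_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_traces = nrow(x$amplitudes),
                 n_points = x$n_points, converged = x$converged,
                 mode = x$mode)
}

#' @rdname tufret-tidiers
#' @method tidy dwell_fit
#' @export
tidy.dwell_fit <- function(x, ...) {
  tibble::tibble(term = c("t_dissoc", "k_dissoc"),
                 estimate = c(x$t_dissoc, x$k_dissoc))
}

#' @rdname tufret-tidiers
#' @method glance dwell_fit
#' @export
glance.dwell_fit <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, min_duration = x$min_duration,
                 converged = x$converged, degenerate = x$degenerate)
}
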