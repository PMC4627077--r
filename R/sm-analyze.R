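#' Detect FRET events in a single-molecule trace
#'
#' Segments a Cy3/Cy5 trace into ribosome-bound FRET events using the 50%
#' total-intensity rule: a frame is in-event when `I_cy3 + I_cy5` is at
#' least `threshold_frac` (default 0.5) of the bound-intensity reference,
#' and contiguous runs of at least `min_frames` (default 2) in-event frames
#' form events.  The reference is estimated from the trace itself as the
#' median total intensity of the frames above an Otsu split of the
#' total-intensity histogram; if the split does not separate two
#' populations (all-background trace) no events are returned.  Pass
#' `reference` explicitly to override the estimator.
#'
#' @param trace An `sm_trace` (or data frame with `frame`, `I_cy3`,
#'   `I_cy5`).
#' @param min_frames Minimum event length in frames (default 2).
#' @param threshold_frac Fraction of the bound reference defining in-event
#'   frames (default 0.5).
#' @param reference Optional known bound-state total intensity.
#' @return A tibble of class `fret_events`, one row per event:
#'   `start_frame`, `end_frame` (half-open, 0-indexed), `n_frames`,
#'   `duration` (s), `mean_fret` (mean acceptor ratio over event frames).
#'   Attributes: `frame_interval`, `reference`, `n_frames_total`.
#'   An all-background trace yields zero rows (not an error).
#' @export
detect_events <- function(trace, min_frames = 2, threshold_frac = 0.5,
                          reference = NULL) {
  d <- as.data.frame(trace)
  if (!all(c("I_cy3", "I_cy5") %in% names(d)))
    stop("trace must have columns `I_cy3` and `I_cy5`", call. = FALSE)
  dt <- attr(trace, "frame_interval") %||% 0.011
  total <- d$I_cy3 + d$I_cy5

  if (is.null(reference)) reference <- estimate_bound_reference(total)
  empty <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                          n_frames = integer(), duration = numeric(),
                          mean_fret = numeric())
  attr(empty, "frame_interval") <- dt
  attr(empty, "reference") <- reference %||% NA_real_
  attr(empty, "n_frames_total") <- length(total)
  class(empty) <- c("fret_events", class(empty))
  if (is.null(reference) || !is.finite(reference) || reference <= 0)
    return(empty)

  in_event <- total >= threshold_frac * reference
  if (!any(in_event)) return(empty)
  r <- rle(in_event)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_frames)
  if (!length(keep)) return(empty)

  ratio <- d$I_cy5 / total
  ev <- tibble::tibble(
    start_frame = starts[keep] - 1L,
    end_frame = ends[keep],            # half-open: [start, end)
    n_frames = r$lengths[keep],
    duration = r$lengths[keep] * dt,
    mean_fret = vapply(keep, function(j)
      mean(ratio[starts[j]:ends[j]]), numeric(1))
  )
  attr(ev, "frame_interval") <- dt
  attr(ev, "reference") <- reference
  attr(ev, "n_frames_total") <- length(total)
  class(ev) <- c("fret_events", class(ev))
  ev
}

# Two-class split of the total-intensity distribution (isodata iteration
# from the half-range midpoint, robust to the small bound fraction typical
# of these traces); returns the median of the upper class, or NULL when the
# classes are not cleanly separated (all-background trace).
estimate_bound_reference <- function(total, max_iter = 50) {
  rng <- range(total)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) return(NULL)
  thr <- mean(rng)
  for (it in seq_len(max_iter)) {
    lo <- total[total <= thr]; hi <- total[total > thr]
    if (!length(hi) || !length(lo)) return(NULL)
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < 1e-9 * diff(rng)) break
    thr <- new_thr
  }
  lo <- total[total <= thr]; hi <- total[total > thr]
  if (!length(hi) || !length(lo)) return(NULL)
  sep <- mean(hi) - mean(lo)
  spread <- stats::sd(lo) + stats::sd(hi)
  if (!is.finite(spread)) spread <- 0
  if (spread > 0 && sep < 3 * spread) return(NULL)
  if (sep <= 0) return(NULL)
  stats::median(hi)
}

#' FRET series with the below-threshold rule applied
#'
#' Returns the trace's FRET ratio with values set to 0 outside detected
#' events, the form used for probability density plots.
#'
#' @param trace An `sm_trace`.
#' @param events Events from [detect_events()] (detected afresh if omitted).
#' @return Numeric vector, one value per frame.
#' @export
fret_zeroed <- function(trace, events = NULL) {
  if (is.null(events)) events <- detect_events(trace)
  d <- as.data.frame(trace)
  total <- d$I_cy3 + d$I_cy5
  ratio <- ifelse(total > 0, d$I_cy5 / total, 0)
  keep <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(events)))
    keep[(events$start_frame[i] + 1L):events$end_frame[i]] <- TRUE
  ifelse(keep, ratio, 0)
}

#' Single-exponential fit of the dwell-time distribution
#'
#' Fits `S(t) = A * exp(-t / t_dissoc)` to the empirical survival function
#' of event durations, reporting the mean occupancy lifetime `t_dissoc` and
#' `k_dissoc = 1 / t_dissoc`.  Durations shorter than `min_duration`
#' (default two camera frames) are excluded as censored — events that short
#' are unreliably detected — and the free amplitude `A` absorbs the
#' truncation.  Each survival point is weighted by the number of events
#' still at risk there (the point is an average over that many events), so
#' the well-populated early part of the curve dominates and the sparse far
#' tail does not.  The optimizer is started from the left-truncated-mean
#' estimate `mean(d) - min_duration`, the exact maximum-likelihood estimate
#' for exponential dwells.
#'
#' @param events A `fret_events` tibble from [detect_events()] (or a bare
#'   numeric vector of durations in s, e.g. pooled across molecules).
#' @param min_duration Censoring threshold (s); defaults to 2 frames when
#'   the frame interval is known, else 0.
#' @return A `dwell_fit`: `t_dissoc` (s), `k_dissoc` (s^-1), `n_events`
#'   (after censoring), `min_duration`, survival-curve residuals,
#'   `converged`, `degenerate`.
#' @export
fit_dwell_distribution <- function(events, min_duration = NULL) {
  if (is.numeric(events)) {
    durations <- events
    dt <- NULL
  } else {
    stopifnot(inherits(events, "fret_events") || "duration" %in% names(events))
    durations <- events$duration
    dt <- attr(events, "frame_interval")
  }
  if (is.null(min_duration))
    min_duration <- if (is.null(dt)) 0 else 2 * dt

  d <- durations[durations >= min_duration]
  if (!length(d)) stop("no events remain after censoring", call. = FALSE)
  if (length(d) < 30)
    warning("only ", length(d), " events: dwell fit will be imprecise",
            call. = FALSE)
  if (length(unique(d)) < 2) {
    warning("fewer than 2 distinct durations: dwell fit is degenerate",
            call. = FALSE)
    return(new_dwell_fit(NA_real_, length(d), min_duration, NA_real_,
                         converged = FALSE, degenerate = TRUE))
  }

  tau0 <- max(mean(d) - min_duration, min(diff(sort(unique(d)))) / 2)
  ts <- sort(unique(d))
  surv <- vapply(ts, function(t0) mean(d >= t0), numeric(1))
  sdat <- data.frame(t = ts, S = surv)
  fit <- try(minpack.lm::nlsLM(
    S ~ A * exp(-t / tau), data = sdat,
    weights = surv * length(d),
    start = list(A = exp(min_duration / tau0), tau = tau0),
    lower = c(A = 0, tau = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(new_dwell_fit(tau0, length(d), min_duration, NA_real_,
                         converged = FALSE, degenerate = FALSE,
                         residuals = rep(NA_real_, nrow(sdat))))
  tau <- stats::coef(fit)[["tau"]]
  new_dwell_fit(tau, length(d), min_duration, stats::coef(fit)[["A"]],
                converged = TRUE, degenerate = FALSE,
                residuals = stats::residuals(fit), survival = sdat)
}

new_dwell_fit <- function(tau, n, min_duration, A, converged, degenerate,
                          residuals = numeric(), survival = NULL) {
  structure(list(t_dissoc = tau, k_dissoc = 1 / tau, n_events = n,
                 min_duration = min_duration, amplitude = A,
                 residuals = residuals, survival = survival,
                 converged = converged, degenerate = degenerate),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("<dwell_fit> t_dissoc = %.4g s (k_dissoc = %.4g s^-1), n = %d events (censored below %.3g s)\n",
              x$t_dissoc, x$k_dissoc, x$n_events, x$min_duration))
  if (x$degenerate) cat("  DEGENERATE\n")
  invisible(x)
}

#' Postsynchronized FRET probability density
#'
#' Two-dimensional histogram of FRET versus time with every trace aligned
#' ("synchronized") at the first or last time point of its FRET events, the
#' standard contour-map representation of single-molecule state occupancy.
#' Each trace contributes its below-threshold-zeroed FRET series; columns
#' are time offsets from the synchronization point, rows are FRET bins, and
#' each column of counts sums to the number of traces covering that offset.
#'
#' @param traces List of `sm_trace` objects.
#' @param sync `"first_point"` (align at the first frame of the first
#'   event) or `"last_point"` (align at the last frame of the last event,
#'   offsets running backward to 0).
#' @param fret_bins Bin edges for the FRET axis (default 50 bins over
#'   -0.2..1.2); out-of-range values are clamped into the edge bins.
#' @param n_frames Number of time columns (default 50).
#' @param events Optional list of pre-detected `fret_events` (parallel to
#'   `traces`); detected afresh when omitted.
#' @param ... Passed to [detect_events()].
#' @return A `fret_density`: list with `counts` and `density` matrices
#'   (FRET bins x time), `fret_breaks`, `offsets` (frames), `time_s`,
#'   `sync`, `n_traces`.
#' @export
density_plot <- function(traces, sync = c("first_point", "last_point"),
                         fret_bins = seq(-0.2, 1.2, length.out = 51),
                         n_frames = 50, events = NULL, ...) {
  sync <- match.arg(sync)
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  if (is.null(events)) events <- lapply(traces, detect_events, ...)
  has_ev <- vapply(events, nrow, integer(1)) > 0
  if (!any(has_ev)) stop("no FRET events detected in any trace", call. = FALSE)

  nb <- length(fret_bins) - 1L
  offsets <- if (sync == "first_point") 0:(n_frames - 1L) else -(n_frames - 1L):0
  counts <- matrix(0, nrow = nb, ncol = n_frames,
                   dimnames = list(NULL, offsets))

  for (i in which(has_ev)) {
    fz <- fret_zeroed(traces[[i]], events[[i]])
    anchor <- if (sync == "first_point") events[[i]]$start_frame[1]
              else events[[i]]$end_frame[nrow(events[[i]])] - 1L
    fr <- seq_along(fz) - 1L
    j <- fr - anchor
    keep <- j >= offsets[1] & j <= offsets[n_frames]
    if (!any(keep)) next
    bin <- findInterval(fz[keep], fret_bins, rightmost.closed = TRUE)
    bin <- pmin(pmax(bin, 1L), nb)
    col <- j[keep] - offsets[1] + 1L
    for (k in seq_along(bin))
      counts[bin[k], col[k]] <- counts[bin[k], col[k]] + 1
  }

  colsum <- colSums(counts)
  density <- sweep(counts, 2, pmax(colsum, 1), "/")
  structure(list(counts = counts, density = density,
                 fret_breaks = fret_bins, offsets = offsets,
                 time_s = offsets * (attr(traces[[which(has_ev)[1]]],
                                          "frame_interval") %||% 0.011),
                 sync = sync, n_traces = sum(has_ev)),
            class = "fret_density")
}

#' @export
print.fret_density <- function(x, ...) {
  cat("<fret_density> sync =", x$sync, "|", x$n_traces, "traces |",
      nrow(x$counts), "FRET bins x", ncol(x$counts), "time columns\n")
  invisible(x)
}

#' Synchronized average FRET trace
#'
#' Averages per-event FRET series aligned at a common boundary.  For
#' `mode = "pre"` events are aligned at their first time point and each
#' series is extended forward past its end holding the FRET value of its
#' last event frame, so every event spans the longest event's extent before
#' averaging.  For `mode = "post"` events are aligned at their last time
#' point and extended backward before their start holding the value of
#' their first event frame.
#'
#' @param traces List of `sm_trace` objects.
#' @param mode `"pre"` or `"post"`.
#' @param events Optional list of pre-detected events.
#' @param ... Passed to [detect_events()].
#' @return Tibble with `offset` (frames; >= 0 for pre, <= 0 for post),
#'   `time_s`, `fret_mean`, `n_events`.
#' @export
synchronized_average <- function(traces, mode = c("pre", "post"),
                                 events = NULL, ...) {
  mode <- match.arg(mode)
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  if (is.null(events)) events <- lapply(traces, detect_events, ...)

  series <- list()
  dt <- 0.011
  for (i in seq_along(traces)) {
    ev <- events[[i]]
    if (!nrow(ev)) next
    dt <- attr(traces[[i]], "frame_interval") %||% dt
    d <- as.data.frame(traces[[i]])
    total <- d$I_cy3 + d$I_cy5
    ratio <- ifelse(total > 0, d$I_cy5 / total, 0)
    for (e in seq_len(nrow(ev)))
      series[[length(series) + 1L]] <-
        ratio[(ev$start_frame[e] + 1L):ev$end_frame[e]]
  }
  if (!length(series)) stop("no FRET events detected in any trace", call. = FALSE)

  L <- max(lengths(series))
  mat <- vapply(series, function(v) {
    if (mode == "pre") c(v, rep(v[length(v)], L - length(v)))
    else c(rep(v[1], L - length(v)), v)
  }, numeric(L))
  mat <- matrix(mat, nrow = L)

  offset <- if (mode == "pre") 0:(L - 1L) else -(L - 1L):0
  tibble::tibble(offset = offset, time_s = offset * dt,
                 fret_mean = rowMeans(mat), n_events = length(series))
}

#' Mean FRET over all in-event frames of a dataset
#'
#' Event-frame-weighted mean of the acceptor ratio, the quantity quoted as
#' the FRET efficiency of the bound state.
#'
#' @param events A `fret_events` tibble or list of them.
#' @return Single number.
#' @export
mean_event_fret <- function(events) {
  if (inherits(events, "fret_events") || is.data.frame(events))
    events <- list(events)
  tot_f <- sum(vapply(events, function(e) sum(e$n_frames), numeric(1)))
  if (tot_f == 0) stop("no event frames", call. = FALSE)
  wsum <- sum(vapply(events, function(e) sum(e$mean_fret * e$n_frames),
                     numeric(1)))
  wsum / tot_f
}
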