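#' Stochastic simulation of one surface-immobilized ribosome
#'
#' Exact continuous-time Markov-chain (Gillespie) simulation of TC binding
#' and processing on a single immobilized 70SIC at the nanomolar TC
#' concentrations of a single-molecule experiment.  TC arrival is
#' pseudo-first-order with rate `k12 * conc_TC`; a bound molecule passes
#' through Complex B (rate `k3` to Complex C) and leaves Complex C at rate
#' `k4 + k4A` (at single-molecule concentrations rebinding of dissociated
#' EF-Tu.GDP* is negligible, so both exit branches are irreversible and
#' merge into the EF-Tu-free PRE state).  All rates are pre-multiplied by
#' `conditions$temperature_scale`.
#'
#' By default entry into Complex B is treated as committed
#' (`committed = TRUE`): Complex B has already hydrolyzed GTP, so the
#' reverse of the lumped binding step cannot regenerate an intact ternary
#' complex, and the bound dwell is the two-stage chain with expectation
#' `1/k3 + 1/(k4 + k4A)`.  Setting `committed = FALSE` enables the
#' `B -> empty` branch at rate `k_m12`, matching the ensemble network.
#'
#' With `recycle = TRUE` (default) the EF-Tu-free states accept new TC
#' arrivals, so a trace can contain repeated binding events; with
#' `recycle = FALSE` the molecule is done after one productive event.
#' EF-G capture (`k_efg * conc_EFG`) converts PRE to POST between events
#' and therefore never alters dwell times.
#'
#' @param rates A [rate_constants()] object (unscaled, 25 C reference).
#' @param conditions A [reaction_conditions()]; `conc_TC` is typically
#'   0.005-0.010 uM and `temperature_scale` 0.5 for a 21 C experiment.
#' @param duration Recording length after injection (s, > 0).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param committed Logical; see Details.
#' @param recycle Logical; see Details.
#' @return An `sm_path`: tibble with columns `time` (s, entry time) and
#'   `state` (one of empty, B, C, PRE, POST), first row `(0, empty)`;
#'   `duration`, scaled rates and conditions attached as attributes.
#' @examples
#' p <- simulate_molecule(rate_constants(50, 0, 9.95, 9.8, k4A = 9.8),
#'                        reaction_conditions(0, 0.01), 60, seed = 1)
#' @export
simulate_molecule <- function(rates, conditions, duration, seed,
                              committed = TRUE, recycle = TRUE) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(conditions, "reaction_conditions"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number of seconds", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("`seed` is required for reproducible simulation", call. = FALSE)
  set.seed(seed)
  sim_path_impl(rates, conditions, duration, committed, recycle)
}

# core SSA loop, assumes RNG state already set
sim_path_impl <- function(rates, conditions, duration, committed, recycle) {
  ts <- conditions$temperature_scale
  k_arr <- rates$k12 * ts * conditions$conc_TC
  k_off <- if (committed) 0 else rates$k_m12 * ts
  k3 <- rates$k3 * ts
  k4A <- if (is.na(rates$k4A)) 0 else rates$k4A * ts
  k_exit <- rates$k4 * ts + k4A
  k_cap <- rates$k_efg * ts * conditions$conc_EFG

  times <- numeric(64); states <- character(64)
  n <- 1L; times[1] <- 0; states[1] <- "empty"
  t <- 0; s <- "empty"
  push <- function(tt, ss) {
    n <<- n + 1L
    if (n > length(times)) {
      times <<- c(times, numeric(length(times)))
      states <<- c(states, character(length(states)))
    }
    times[n] <<- tt; states[n] <<- ss
  }

  repeat {
    out_rates <- switch(s,
      empty = c(B = k_arr),
      B     = c(C = k3, empty = k_off),
      C     = c(PRE = k_exit),
      PRE   = c(POST = k_cap, B = if (recycle) k_arr else 0),
      POST  = c(B = if (recycle) k_arr else 0)
    )
    out_rates <- out_rates[out_rates > 0]
    if (!length(out_rates)) break
    lambda <- sum(out_rates)
    t <- t + stats::rexp(1, lambda)
    if (t >= duration) break
    s <- if (length(out_rates) == 1L) names(out_rates) else
      sample(names(out_rates), 1L, prob = out_rates)
    push(t, s)
  }

  out <- tibble::tibble(time = times[seq_len(n)], state = states[seq_len(n)])
  attr(out, "duration") <- duration
  attr(out, "conditions") <- conditions
  attr(out, "rates") <- rates
  class(out) <- c("sm_path", class(out))
  out
}

#' State of a molecule at given times
#'
#' Evaluates the piecewise-constant state path at arbitrary times.
#'
#' @param path An `sm_path`.
#' @param times Numeric vector of times in `[0, duration)`.
#' @return Character vector of states.
#' @export
state_at <- function(path, times) {
  stopifnot(inherits(path, "sm_path"))
  idx <- findInterval(times, path$time)
  idx[idx < 1L] <- 1L
  path$state[idx]
}

#' EF-Tu-bound intervals of a state path
#'
#' Contiguous intervals during which the molecule is in Complex B or
#' Complex C (the FRET-on states; Complex C is too short-lived at camera
#' resolution to render as a distinct level).
#'
#' @param path An `sm_path`.
#' @return Tibble with columns `start`, `end` (s, half-open), `duration`.
#' @export
bound_intervals <- function(path) {
  stopifnot(inherits(path, "sm_path"))
  dur <- attr(path, "duration")
  bound <- path$state %in% c("B", "C")
  if (!any(bound))
    return(tibble::tibble(start = numeric(), end = numeric(),
                          duration = numeric()))
  r <- rle(bound)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  on <- which(r$values)
  start <- path$time[starts_idx[on]]
  end <- ifelse(ends_idx[on] < nrow(path), path$time[ends_idx[on] + 1L], dur)
  tibble::tibble(start = start, end = end, duration = end - start)
}

#' Render a camera-frame Cy3/Cy5 single-molecule trace
#'
#' Converts a state path into per-frame donor/acceptor intensities at the
#' camera's integration time.  While EF-Tu is bound (Complex B or C) the
#' molecule emits `I_Cy5 = E * I_tot` and `I_Cy3 = (1 - E) * I_tot`;
#' unbound frames emit background 0.  A frame containing a jump gets the
#' time-weighted average of the two levels (within-frame occupancy
#' weighting), then i.i.d. Gaussian noise is added per channel.  The FRET
#' ratio `I_Cy5 / (I_Cy5 + I_Cy3)` is reported, set to 0 on frames whose
#' total intensity falls below 50% of the nominal bound intensity (the
#' rendered trace applies the rule with the known `total_intensity`;
#' [detect_events()] re-estimates the reference from the data).
#'
#' Recording starts `pre_injection` seconds before the injection that
#' starts the path clock, so `time_s = (frame - injection_frame) *
#' frame_interval`.
#'
#' @param path An `sm_path` from [simulate_molecule()].
#' @param efficiency Bound-state FRET efficiency E, 0 < E < 1.
#' @param total_intensity Bound-state total emission (counts/frame,
#'   default 1000).
#' @param noise_sigma Gaussian noise s.d. per channel (counts, default 50;
#'   0 for noiseless).
#' @param frame_interval Camera integration time (s, default 0.011).
#' @param pre_injection Seconds of recording before injection (default 5).
#' @param seed Integer seed for the frame noise (required when
#'   `noise_sigma > 0`).
#' @return An `sm_trace`: tibble with columns `frame` (0-indexed),
#'   `time_s`, `I_cy3`, `I_cy5`, `fret`; attributes `frame_interval`,
#'   `injection_frame`, `efficiency`, `total_intensity`, `noise_sigma` and
#'   `truth` (the ground-truth bound intervals).
#' @export
render_trace <- function(path, efficiency, total_intensity = 1000,
                         noise_sigma = 50, frame_interval = 0.011,
                         pre_injection = 5, seed = NULL) {
  stopifnot(inherits(path, "sm_path"))
  if (!is.numeric(efficiency) || efficiency <= 0 || efficiency >= 1)
    stop("`efficiency` must lie strictly between 0 and 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("`seed` is required when noise_sigma > 0", call. = FALSE)
    set.seed(seed)
  }
  duration <- attr(path, "duration")
  dt <- frame_interval
  inj <- as.integer(round(pre_injection / dt))
  n_frames <- inj + as.integer(ceiling(duration / dt - 1e-9))

  w <- frame_occupancy(bound_intervals(path), n_frames, inj, dt)

  I5 <- w * efficiency * total_intensity
  I3 <- w * (1 - efficiency) * total_intensity
  if (noise_sigma > 0) {
    I3 <- I3 + stats::rnorm(n_frames, 0, noise_sigma)
    I5 <- I5 + stats::rnorm(n_frames, 0, noise_sigma)
  }
  total <- I3 + I5
  fret <- ifelse(total >= 0.5 * total_intensity, I5 / total, 0)

  out <- tibble::tibble(frame = seq_len(n_frames) - 1L,
                        time_s = (seq_len(n_frames) - 1L - inj) * dt,
                        I_cy3 = I3, I_cy5 = I5, fret = fret)
  attr(out, "frame_interval") <- dt
  attr(out, "injection_frame") <- inj
  attr(out, "efficiency") <- efficiency
  attr(out, "total_intensity") <- total_intensity
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "truth") <- bound_intervals(path)
  class(out) <- c("sm_trace", class(out))
  out
}

# fraction of each frame spent bound; frame f covers
# [(f - inj) * dt, (f - inj + 1) * dt) on the injection clock
frame_occupancy <- function(intervals, n_frames, inj, dt) {
  w <- numeric(n_frames)
  if (!nrow(intervals)) return(w)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    f0 <- max(0L, inj + as.integer(floor(s / dt + 1e-12)))
    f1 <- min(n_frames - 1L, inj + as.integer(ceiling(e / dt - 1e-12)) - 1L)
    if (f1 < f0) next
    fr <- f0:f1
    lo <- (fr - inj) * dt
    hi <- lo + dt
    w[fr + 1L] <- w[fr + 1L] + (pmin(e, hi) - pmax(s, lo)) / dt
  }
  pmin(w, 1)
}

#' @export
print.sm_trace <- function(x, ...) {
  cat("<sm_trace>", nrow(x), "frames at", attr(x, "frame_interval") * 1000,
      "ms | injection at frame", attr(x, "injection_frame"),
      "| E =", attr(x, "efficiency"),
      "| noise_sigma =", attr(x, "noise_sigma"), "\n")
  NextMethod()
}
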