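#' Published-style generating rate constants
#'
#' The two reference parameter sets used throughout the package's recovery
#' studies, corresponding to the two labeled-TC reaction series that were
#' globally fitted: series 1 (quencher-labeled EF-Tu reacting with
#' Cy3-L11 ribosomes; binding, accommodation and Pi-release channels) and
#' series 2 (quencher-EF-Tu/Cy3-tRNA TC reacting with unlabeled ribosomes;
#' tRNA-recovery and accommodation channels).  `k_m12` is stored as
#' `Kd * k12`.
#'
#' @param series 1 or 2.
#' @return A [rate_constants()] object: series 1 gives `k12 = 36`,
#'   `Kd = 0.10` (so `k_m12 = 3.6`), `k3 = 15.4`, `k4 = 19.6`; series 2
#'   gives `k12 = 100`, `Kd = 1.2` (`k_m12 = 120`), `k3 = 19.9`,
#'   `k4 = 19.6`.
#' @export
reference_rates <- function(series = 1) {
  if (series == 1) rate_constants(k12 = 36, k_m12 = 36 * 0.10, k3 = 15.4, k4 = 19.6)
  else if (series == 2) rate_constants(k12 = 100, k_m12 = 100 * 1.2, k3 = 19.9, k4 = 19.6)
  else stop("`series` must be 1 or 2", call. = FALSE)
}

#' Default stopped-flow output time grid
#'
#' Dense early sampling (0.5 ms out to 50 ms) to resolve the fast binding
#' phase, then progressively coarser points out to `t_max`, mimicking the
#' logarithmic sampling of a stopped-flow instrument.
#'
#' @param t_max Final time (s, default 2).
#' @return Strictly increasing numeric vector starting at 0.
#' @export
default_time_grid <- function(t_max = 2) {
  g <- c(seq(0, 0.05, by = 5e-4),
         seq(0.052, 0.3, by = 2e-3),
         seq(0.305, t_max, by = 0.01))
  unique(g[g <= t_max])
}

#' Configuration for a synthetic ensemble dataset
#'
#' Captures everything needed to generate a multi-channel, multi-
#' concentration stopped-flow dataset: the generating rate constants, the
#' concentration grid (all combinations of the supplied vectors), the
#' channel list, per-channel noise, and the output time grid.  The seed is
#' mandatory and is echoed verbatim into every manifest.
#'
#' @param seed Integer seed.
#' @param rates Generating [rate_constants()].
#' @param mode `"collapsed"` or `"full"` network.
#' @param channels Character vector of observable channels.
#' @param conc_70SIC,conc_TC,conc_EFG Concentration vectors (uM); the
#'   condition grid is their crossing.
#' @param temperature_scale Uniform rate multiplier (default 1).
#' @param noise_sigma Gaussian noise s.d.: a single number (a.u.), a named
#'   per-channel vector, or `NULL` for the default of 1.5% of each trace's
#'   dynamic range.
#' @param time_grid Output times (default [default_time_grid()]).
#' @param fit Optional list describing the intended recovery fit
#'   (`mode`, `free`, `fixed`, `start`), used by [recover()].
#' @return An `ensemble_config` object.
#' @export
ensemble_config <- function(seed,
                            rates = reference_rates(1),
                            mode = c("collapsed", "full"),
                            channels = c("L11_Cy3", "prf", "PBP"),
                            conc_70SIC = 0.1,
                            conc_TC = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2),
                            conc_EFG = 0,
                            temperature_scale = 1,
                            noise_sigma = NULL,
                            time_grid = default_time_grid(),
                            fit = NULL) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "rate_constants"))
  bad <- setdiff(channels, observable_channels())
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), rates = rates, mode = mode,
                 channels = channels, conc_70SIC = conc_70SIC,
                 conc_TC = conc_TC, conc_EFG = conc_EFG,
                 temperature_scale = temperature_scale,
                 noise_sigma = noise_sigma, time_grid = time_grid,
                 fit = fit),
            class = "ensemble_config")
}

#' Generate a synthetic ensemble dataset
#'
#' Runs the forward model for every channel at every condition of the
#' config's concentration grid and adds i.i.d. Gaussian noise.  Fully
#' deterministic given the config seed (R's default Mersenne-Twister
#' stream, consumed in a fixed trace order).  With `noise_sigma = 0` the
#' traces equal the [project_observable()] output exactly.
#'
#' @param config An [ensemble_config()].
#' @return A dataset tibble (one row per trace: `channel`, `conc_70SIC`,
#'   `conc_TC`, `conc_EFG`, `temperature_scale`, `noise_sigma`, list-column
#'   `data`) ready for [global_fit()]; the config is attached as attribute
#'   `manifest`.
#' @export
gen_ensemble_dataset <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  set.seed(config$seed)
  net <- suppressMessages(build_network(config$rates, config$mode))
  grid <- expand.grid(conc_70SIC = config$conc_70SIC,
                      conc_TC = config$conc_TC,
                      conc_EFG = config$conc_EFG,
                      KEEP.OUT.ATTRS = FALSE)

  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- reaction_conditions(grid$conc_70SIC[g], grid$conc_TC[g],
                                grid$conc_EFG[g], config$temperature_scale)
    traj <- integrate_ensemble(net, cond, config$time_grid)
    for (ch in config$channels) {
      tr <- project_observable(traj, ch)
      sigma <- resolve_sigma(config$noise_sigma, ch, tr$fluorescence_au)
      y <- tr$fluorescence_au
      if (sigma > 0) y <- y + stats::rnorm(length(y), 0, sigma)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = ch, conc_70SIC = cond$conc_70SIC, conc_TC = cond$conc_TC,
        conc_EFG = cond$conc_EFG,
        temperature_scale = config$temperature_scale, noise_sigma = sigma,
        data = list(tibble::tibble(time_s = tr$time_s, fluorescence_au = y)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "manifest") <- manifest_of(config)
  out
}

resolve_sigma <- function(noise_sigma, channel, y) {
  if (is.null(noise_sigma)) return(0.015 * diff(range(y)))
  if (!is.null(names(noise_sigma))) {
    if (!channel %in% names(noise_sigma))
      stop("no noise_sigma entry for channel ", channel, call. = FALSE)
    return(unname(noise_sigma[[channel]]))
  }
  noise_sigma
}

#' Configuration for a synthetic single-molecule FRET dataset
#'
#' Defaults reproduce the single-molecule study conditions: series-2
#' generating constants with the reversible exit branch opened at
#' `k4A = k4` (the branch is resolvable only at single-molecule
#' concentrations, where it is effectively irreversible), all rates halved
#' via `temperature_scale = 0.5` (21 C vs the 25 C ensemble reference),
#' 10 nM TC injected at t = 0 after 5 s of pre-injection recording, 60 s
#' recordings at 11 ms/frame, bound-state FRET efficiency 0.90
#' (EF-Tu-Cy3 / L11-Cy5 pair; use 0.69 for the intra-TC pair), 1000
#' counts/frame and 50-count Gaussian channel noise.
#'
#' @param seed Integer seed.
#' @param rates Generating [rate_constants()] (default series-2 constants
#'   with `k4A = k4 = 19.6`).
#' @param n_molecules Number of molecules (> 0).
#' @param conc_TC TC concentration (uM; default 0.010 = 10 nM).
#' @param conc_EFG EF-G.GTP concentration (uM, default 0).
#' @param temperature_scale Default 0.5.
#' @param efficiency Bound-state FRET efficiency (default 0.90).
#' @param total_intensity Counts/frame (default 1000).
#' @param noise_sigma Per-channel Gaussian noise (counts, default 50).
#' @param duration Recording length after injection (s, default 60).
#' @param pre_injection Pre-injection recording (s, default 5).
#' @param frame_interval Camera integration time (s, default 0.011).
#' @param committed,recycle Passed to [simulate_molecule()].
#' @return An `smfret_config` object.
#' @export
smfret_config <- function(seed,
                          rates = rate_constants(k12 = 100, k_m12 = 120,
                                                 k3 = 19.9, k4 = 19.6,
                                                 k4A = 19.6),
                          n_molecules = 100,
                          conc_TC = 0.010, conc_EFG = 0,
                          temperature_scale = 0.5,
                          efficiency = 0.90, total_intensity = 1000,
                          noise_sigma = 50, duration = 60,
                          pre_injection = 5, frame_interval = 0.011,
                          committed = TRUE, recycle = TRUE) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!is.numeric(n_molecules) || n_molecules <= 0)
    stop("`n_molecules` must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed), rates = rates,
                 n_molecules = as.integer(n_molecules),
                 conc_TC = conc_TC, conc_EFG = conc_EFG,
                 temperature_scale = temperature_scale,
                 efficiency = efficiency, total_intensity = total_intensity,
                 noise_sigma = noise_sigma, duration = duration,
                 pre_injection = pre_injection,
                 frame_interval = frame_interval,
                 committed = committed, recycle = recycle),
            class = "smfret_config")
}

#' Generate a synthetic single-molecule FRET dataset
#'
#' Simulates `n_molecules` independent state paths, renders each as a
#' camera-frame trace, and (optionally) analyzes each trace as it is made.
#' Per-molecule seeds are drawn once from the config seed, so the dataset
#' is fully deterministic and any single molecule can be regenerated.
#' Ground-truth bound intervals for every molecule are stored in the
#' manifest; recovery tests read truth only from there.
#'
#' @param config An [smfret_config()].
#' @param collect `"all"` keeps the rendered traces (memory ~ n_molecules x
#'   n_frames); `"events"` runs [detect_events()] per molecule and keeps
#'   only the event tables — use this for large dwell-time studies.
#' @return List of class `smfret_dataset`: `traces` (list of `sm_trace`, or
#'   `NULL`), `events` (list of `fret_events`, one per molecule),
#'   `truth` (tibble `molecule`, `start`, `end`, `duration`), `manifest`.
#' @export
gen_smfret_dataset <- function(config, collect = c("all", "events")) {
  stopifnot(inherits(config, "smfret_config"))
  collect <- match.arg(collect)
  set.seed(config$seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, config$n_molecules)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, config$n_molecules)

  cond <- reaction_conditions(0, config$conc_TC, config$conc_EFG,
                              config$temperature_scale)
  traces <- if (collect == "all") vector("list", config$n_molecules)
  events <- vector("list", config$n_molecules)
  truth <- vector("list", config$n_molecules)

  for (i in seq_len(config$n_molecules)) {
    p <- simulate_molecule(config$rates, cond, config$duration,
                           seed = sim_seeds[i],
                           committed = config$committed,
                           recycle = config$recycle)
    tr <- render_trace(p, efficiency = config$efficiency,
                       total_intensity = config$total_intensity,
                       noise_sigma = config$noise_sigma,
                       frame_interval = config$frame_interval,
                       pre_injection = config$pre_injection,
                       seed = noise_seeds[i])
    ti <- bound_intervals(p)
    truth[[i]] <- if (nrow(ti))
      tibble::tibble(molecule = i, start = ti$start, end = ti$end,
                     duration = ti$duration)
    events[[i]] <- detect_events(tr)
    if (collect == "all") traces[[i]] <- tr
  }

  structure(list(traces = traces, events = events,
                 truth = dplyr::bind_rows(truth),
                 manifest = manifest_of(config)),
            class = "smfret_dataset")
}

#' Pooled event durations of a single-molecule dataset
#'
#' @param dataset An `smfret_dataset`.
#' @return `fret_events`-compatible tibble of all events across molecules.
#' @export
pooled_events <- function(dataset) {
  stopifnot(inherits(dataset, "smfret_dataset"))
  nonempty <- dataset$events[vapply(dataset$events, nrow, integer(1)) > 0]
  if (!length(nonempty)) stop("no events in dataset", call. = FALSE)
  out <- dplyr::bind_rows(lapply(seq_along(nonempty), function(i)
    dplyr::mutate(tibble::as_tibble(nonempty[[i]]), molecule = i)))
  attr(out, "frame_interval") <- attr(nonempty[[1]], "frame_interval")
  class(out) <- c("fret_events", class(out))
  out
}

#' Generate an apparent-rate versus concentration table
#'
#' Two routes.  `route = "mm"` evaluates the Michaelis-Menten form
#' `Vmax * S / (KM + S)` on the concentration grid (plus optional Gaussian
#' noise) — the direct emulation of a published rate-vs-concentration
#' panel.  `route = "forward"` generates noiseless forward-model traces
#' over a 70SIC concentration grid at fixed TC and fits each with
#' [fit_monoexponential()], yielding end-to-end apparent rates per channel
#' (e.g. the accommodation rate from `prf` and the EF-Tu:tRNA separation
#' rate from `tRNA_Cy3`).
#'
#' @param route `"mm"` or `"forward"`.
#' @param concentrations Concentration grid (uM, default the five-point
#'   0.2-1.2 grid).
#' @param Vmax,KM MM-route generating parameters (defaults: the
#'   Cy3-channel values 8.2 s^-1 and 0.78 uM).
#' @param noise_sigma MM-route Gaussian noise on the rates (s^-1, default 0).
#' @param seed Seed (required when `noise_sigma > 0`).
#' @param rates Forward-route generating [rate_constants()].
#' @param mode Forward-route network mode (default `"full"` so that the
#'   EF-Tu departure branch is explicit).
#' @param channels Forward-route channels (default `prf` and `tRNA_Cy3`).
#' @param conc_TC Forward-route fixed TC concentration (uM, default 0.1).
#' @param conc_EFG Forward-route EF-G concentration (uM, default 0).
#' @param time_grid Forward-route output grid.
#' @return Tibble with columns `concentration`, `channel`, `rate`.
#' @export
gen_rate_vs_concentration <- function(route = c("mm", "forward"),
                                      concentrations = c(0.2, 0.4, 0.6, 0.9, 1.2),
                                      Vmax = 8.2, KM = 0.78,
                                      noise_sigma = 0, seed = NULL,
                                      rates = rate_constants(100, 120, 19.9, 19.6,
                                                             k4A = 19.6,
                                                             k_m4A = 100,
                                                             k_efg = 2),
                                      mode = "full",
                                      channels = c("prf", "tRNA_Cy3"),
                                      conc_TC = 0.1, conc_EFG = 0,
                                      time_grid = default_time_grid()) {
  route <- match.arg(route)
  if (route == "mm") {
    k <- Vmax * concentrations / (KM + concentrations)
    if (noise_sigma > 0) {
      if (is.null(seed)) stop("`seed` required when noise_sigma > 0", call. = FALSE)
      set.seed(seed)
      k <- k + stats::rnorm(length(k), 0, noise_sigma)
    }
    return(tibble::tibble(concentration = concentrations, channel = "mm",
                          rate = k))
  }
  net <- suppressMessages(build_network(rates, mode))
  rows <- list()
  for (S in concentrations) {
    cond <- reaction_conditions(conc_70SIC = S, conc_TC = conc_TC,
                                conc_EFG = conc_EFG)
    traj <- integrate_ensemble(net, cond, time_grid)
    for (ch in channels) {
      f <- suppressWarnings(fit_monoexponential(project_observable(traj, ch)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        concentration = S, channel = ch, rate = f$k_prime)
    }
  }
  dplyr::bind_rows(rows)
}

manifest_of <- function(config) {
  m <- unclass(config)
  if (inherits(m$rates, "rate_constants")) m$rates <- unclass(m$rates)
  m$package_version <- as.character(utils::packageVersion("tufret"))
  m$class <- class(config)[1]
  m
}
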