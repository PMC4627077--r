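#' Write a trace to CSV
#'
#' Ensemble traces are written as `time_s,fluorescence_au` and
#' single-molecule traces as `frame,time_s,I_cy3,I_cy5,fret`, preceded by
#' `#`-prefixed header comment lines carrying the metadata (channel,
#' concentrations, noise, frame interval, injection frame, seed) needed to
#' reconstruct the object's attributes on read.
#'
#' @param trace An `ensemble_trace` or `sm_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "sm_trace")) {
    hdr <- c("# tufret smfret trace",
             paste0("# frame_interval_s: ", attr(trace, "frame_interval")),
             paste0("# injection_frame: ", attr(trace, "injection_frame")),
             paste0("# efficiency: ", attr(trace, "efficiency")),
             paste0("# total_intensity: ", attr(trace, "total_intensity")),
             paste0("# noise_sigma: ", attr(trace, "noise_sigma")))
    cols <- c("frame", "time_s", "I_cy3", "I_cy5", "fret")
  } else if (inherits(trace, "ensemble_trace")) {
    cond <- attr(trace, "conditions")
    hdr <- c("# tufret ensemble trace",
             paste0("# channel: ", attr(trace, "channel")),
             paste0("# conc_70SIC_uM: ", cond$conc_70SIC),
             paste0("# conc_TC_uM: ", cond$conc_TC),
             paste0("# conc_EFG_uM: ", cond$conc_EFG),
             paste0("# temperature_scale: ", cond$temperature_scale),
             paste0("# noise_sigma: ", attr(trace, "noise_sigma")),
             paste0("# seed: ", attr(trace, "seed") %||% NA))
    cols <- c("time_s", "fluorescence_au")
  } else stop("`trace` must be an ensemble_trace or sm_trace", call. = FALSE)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(trace)[cols], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' The trace kind is recognized from the first header line; metadata
#' comments are restored as attributes.  Malformed files (missing columns,
#' non-monotone time) raise an error naming the offending line.
#'
#' @param path File path.
#' @return An `ensemble_trace` or `sm_trace`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    stop("trace file does not exist: ", path, call. = FALSE)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, is_hdr) - 1L
  meta <- list()
  for (l in lines[seq_len(n_hdr)][-1]) {
    kv <- sub("^#\\s*", "", l)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  d <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"))
  kind <- if (n_hdr >= 1 && grepl("smfret", lines[1])) "sm" else "ensemble"

  num <- function(key, default = NA_real_) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (length(v) && !is.na(v)) v else default
  }

  if (kind == "ensemble") {
    need <- c("time_s", "fluorescence_au")
    if (!all(need %in% names(d)))
      stop("missing column(s) ", paste(setdiff(need, names(d)), collapse = ", "),
           " in ", path, " (data header at line ", n_hdr + 1, ")", call. = FALSE)
    bad <- which(diff(d$time_s) <= 0)
    if (length(bad))
      stop("non-monotone time in ", path, " at data line ", bad[1] + 1,
           " (file line ", n_hdr + 1 + bad[1] + 1, ")", call. = FALSE)
    cond <- reaction_conditions(num("conc_70SIC_uM", 0), num("conc_TC_uM", 0),
                                num("conc_EFG_uM", 0),
                                num("temperature_scale", 1))
    new_ensemble_trace(d$time_s, d$fluorescence_au,
                       channel = meta[["channel"]] %||% NA_character_,
                       conditions = cond,
                       noise_sigma = num("noise_sigma", 0),
                       seed = num("seed"))
  } else {
    need <- c("frame", "time_s", "I_cy3", "I_cy5", "fret")
    if (!all(need %in% names(d)))
      stop("missing column(s) ", paste(setdiff(need, names(d)), collapse = ", "),
           " in ", path, " (data header at line ", n_hdr + 1, ")", call. = FALSE)
    bad <- which(diff(d$time_s) <= 0)
    if (length(bad))
      stop("non-monotone time in ", path, " at data line ", bad[1] + 1,
           call. = FALSE)
    out <- tibble::as_tibble(d[need])
    attr(out, "frame_interval") <- num("frame_interval_s", 0.011)
    attr(out, "injection_frame") <- as.integer(num("injection_frame", 0))
    attr(out, "efficiency") <- num("efficiency")
    attr(out, "total_intensity") <- num("total_intensity")
    attr(out, "noise_sigma") <- num("noise_sigma", 0)
    class(out) <- c("sm_trace", class(out))
    out
  }
}

#' Read a rate-constants / conditions config file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with exactly the field names of
#' [rate_constants()] and [reaction_conditions()]; unknown keys are
#' rejected.
#'
#' @param path File path.
#' @return A list with elements `rates` ([rate_constants()]) and, when
#'   present, `conditions` ([reaction_conditions()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  known_top <- c("rates", "conditions")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- list()
  if (!is.null(raw$rates)) {
    raw$rates <- raw$rates[!vapply(raw$rates, is.null, logical(1))]
    allowed <- names(formals(rate_constants))
    unknown <- setdiff(names(raw$rates), allowed)
    if (length(unknown))
      stop("unknown rate key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$rates <- do.call(rate_constants, raw$rates)
  }
  if (!is.null(raw$conditions)) {
    allowed <- names(formals(reaction_conditions))
    unknown <- setdiff(names(raw$conditions), allowed)
    if (length(unknown))
      stop("unknown condition key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$conditions <- do.call(reaction_conditions, raw$conditions)
  }
  out
}

#' Write a config file
#'
#' @param rates A [rate_constants()] object.
#' @param conditions Optional [reaction_conditions()].
#' @param path Output path (`.json`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(rates, conditions = NULL, path) {
  stopifnot(inherits(rates, "rate_constants"))
  rl <- unclass(rates)
  x <- list(rates = rl[!vapply(rl, is.na, logical(1))])  # NA = unspecified
  if (!is.null(conditions)) x$conditions <- unclass(conditions)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' End-to-end generate / fit / report recovery run
#'
#' Drives the whole pipeline on a synthetic config: generates the dataset,
#' runs the appropriate fitter, and compares the recovered parameters with
#' the generating truth carried by the manifest.  For an
#' [ensemble_config()] this is [gen_ensemble_dataset()] followed by
#' [global_fit()] (fit specification taken from `config$fit`, defaulting to
#' free `k12, k_m12, k3` with `k4` fixed at its generating value); for an
#' [smfret_config()] it is [gen_smfret_dataset()] followed by
#' [fit_dwell_distribution()], compared against the analytic mean occupancy
#' `1/k3 + 1/(k4 + k4A)` at the config's temperature scale.
#'
#' @param config An [ensemble_config()] or [smfret_config()].
#' @param tolerance Relative tolerance for the pass/fail verdict
#'   (default 0.10).
#' @return A `run_report`: tibble with columns `parameter`, `truth`,
#'   `estimate`, `rel_error`, `tolerance`, `pass`, plus attributes `fit`,
#'   `manifest`, `runtime_s` and `passed` (all rows pass).
#' @export
recover <- function(config, tolerance = 0.10) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(config, "ensemble_config")) {
    ds <- gen_ensemble_dataset(config)
    spec <- config$fit %||% list(
      mode = config$mode,
      free = c("k12", "k_m12", "k3"),
      fixed = c(k4 = config$rates$k4))
    fit <- global_fit(ds, mode = spec$mode %||% config$mode,
                      free = spec$free,
                      fixed = spec$fixed,
                      start = spec$start %||% NULL)
    truth <- vapply(spec$free, function(nm) config$rates[[nm]], numeric(1))
    est <- vapply(spec$free, function(nm) fit$rates[[nm]], numeric(1))
    report <- tibble::tibble(parameter = spec$free, truth = truth,
                             estimate = est,
                             rel_error = abs(est - truth) / abs(truth))
  } else if (inherits(config, "smfret_config")) {
    ds <- gen_smfret_dataset(config, collect = "events")
    dwell <- suppressWarnings(fit_dwell_distribution(pooled_events(ds)))
    r <- scale_rates(config$rates, config$temperature_scale)
    k4A <- if (is.na(r$k4A)) 0 else r$k4A
    truth <- 1 / r$k3 + 1 / (r$k4 + k4A)
    report <- tibble::tibble(parameter = "t_dissoc", truth = truth,
                             estimate = dwell$t_dissoc,
                             rel_error = abs(dwell$t_dissoc - truth) / truth)
    fit <- dwell
  } else stop("`config` must be an ensemble_config or smfret_config",
              call. = FALSE)

  report$tolerance <- tolerance
  report$pass <- report$rel_error <= tolerance
  attr(report, "fit") <- fit
  attr(report, "manifest") <- manifest_of(config)
  attr(report, "runtime_s") <- proc.time()[["elapsed"]] - t0
  attr(report, "passed") <- all(report$pass)
  class(report) <- c("run_report", class(report))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", if (attr(x, "passed")) "PASS" else "FAIL",
      sprintf("(%.1f s)\n", attr(x, "runtime_s")))
  NextMethod()
}
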