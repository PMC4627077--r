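#' Global fit of scheme rate constants across channels and concentrations
#'
#' Simultaneous least-squares estimation of the microscopic rate constants
#' from a set of fluorescence traces spanning reporter channels and
#' concentration series.  The rate constants are shared across all traces;
#' each trace gets its own baseline and amplitude, which are profiled out by
#' linear least squares at every iteration (variable projection).  The rates
#' are optimized on the log scale with a Levenberg-Marquardt trust-region
#' solver from a deterministic, log-spaced multi-start (no random numbers),
#' so repeated fits are bit-identical.
#'
#' In the usual reporting mode the collapsed network is used (single
#' irreversible EF-Tu.GDP exit `k4`), the simplification under which the
#' published-style constants are defined: the Complex C branch point is not
#' resolved by ensemble data, so Complex C is assumed dominant and the
#' fitted `k4` is a lower limit on the true exit rate.  `k4` may be held
#' fixed via `fixed=`.
#'
#' Before fitting, a quantitative identifiability check is run: the
#' finite-difference sensitivity of the profiled residuals to each free
#' log-rate is assembled into a Jacobian whose singular values must not
#' reveal a numerically dead or fully collinear direction; such requests are
#' refused with a diagnostic naming the offending parameters.  A warning
#' (not an error) is issued when `k12`/`k_m12` are freed without a
#' binding-sensitive (L11_Cy3) channel, since their information then enters
#' only indirectly and confidence intervals will be wide.
#'
#' @param dataset A trace dataset: tibble with columns `channel`,
#'   `conc_70SIC`, `conc_TC`, optional `conc_EFG` and `temperature_scale`,
#'   and a list-column `data` of tibbles (`time_s`, `fluorescence_au`); or a
#'   list of `ensemble_trace` objects (see [as_trace_dataset()]).
#' @param mode `"collapsed"` (default) or `"full"` network.
#' @param free Character vector of rate names to estimate (subset of
#'   `k12, k_m12, k3, k4, k4A, k_m4A`).
#' @param fixed Named numeric vector of rates held at the given values; every
#'   rate of the mode not in `free` must appear here (unused full-mode rates
#'   default to 0).
#' @param start Optional named numeric vector of starting values for the
#'   free rates (defaults to 10 in each rate's natural unit).
#' @param n_starts Number of deterministic multi-start points (>= 8 by
#'   default, log-spaced perturbations of `start`).
#' @param refine_top How many of the best starts to refine with the local
#'   optimizer (default 3; refinement stops early once the objective falls
#'   below `1e-12` of the total signal sum of squares, as happens for
#'   noiseless self-generated data).
#' @return A `global_fit` object: `rates` (recovered [rate_constants()]),
#'   `free`, `fixed`, `amplitudes` (per-trace tibble with `F0` and
#'   `amplitude`), `objective` (residual sum of squares), `trace_rss`,
#'   `converged`, diagnostics.  Use [generics::tidy()] / [generics::glance()].
#' @export
global_fit <- function(dataset,
                       mode = c("collapsed", "full"),
                       free = c("k12", "k_m12", "k3"),
                       fixed = c(k4 = 19.6),
                       start = NULL, n_starts = 8, refine_top = 3) {
  mode <- match.arg(mode)
  ds <- as_trace_dataset(dataset)
  rate_names <- if (mode == "collapsed") c("k12", "k_m12", "k3", "k4")
                else c("k12", "k_m12", "k3", "k4", "k4A", "k_m4A")

  free <- unique(free)
  if (!all(free %in% rate_names))
    stop("unknown or out-of-mode free parameter(s): ",
         paste(setdiff(free, rate_names), collapse = ", "), call. = FALSE)
  if (length(intersect(free, names(fixed))))
    stop("parameter(s) both free and fixed: ",
         paste(intersect(free, names(fixed)), collapse = ", "), call. = FALSE)
  missing <- setdiff(rate_names, c(free, names(fixed)))
  if (mode == "full") {
    # unspecified branch rates default to 0 rather than erroring
    fixed <- c(fixed, stats::setNames(rep(0, length(intersect(missing, c("k4A", "k_m4A")))),
                                      intersect(missing, c("k4A", "k_m4A"))))
    missing <- setdiff(rate_names, c(free, names(fixed)))
  }
  if (length(missing))
    stop("rate(s) neither free nor fixed: ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (any(c("k12", "k_m12") %in% free) && !"L11_Cy3" %in% ds$channel)
    warning("k12/k_m12 are free but no binding-sensitive (L11_Cy3) channel ",
            "is present; these rates are informed only indirectly and their ",
            "uncertainties will be large", call. = FALSE)

  if (is.null(start)) start <- stats::setNames(rep(10, length(free)), free)
  if (!all(free %in% names(start)))
    stop("`start` must name every free parameter", call. = FALSE)
  start <- start[free]

  prep <- prepare_dataset(ds)
  total_ss <- sum(vapply(prep$traces, function(tr) sum(tr$y^2), numeric(1)))

  make_rates <- function(theta) {
    vals <- c(stats::setNames(exp(theta), free), fixed)
    rate_constants(k12 = vals[["k12"]], k_m12 = vals[["k_m12"]],
                   k3 = vals[["k3"]], k4 = vals[["k4"]],
                   k4A = vget(vals, "k4A", 0),
                   k_m4A = if (mode == "full") vget(vals, "k_m4A", 0) else NA_real_,
                   k_efg = vget(fixed, "k_efg", 0))
  }

  n_resid <- sum(vapply(prep$traces, function(tr) length(tr$y), numeric(1)))
  residual_fun <- function(theta) {
    rates <- make_rates(theta)
    net <- suppressMessages(build_network(rates, mode))
    out <- try(unlist(lapply(prep$groups, function(g) {
      traj <- suppressWarnings(integrate_ensemble(net, g$conditions, g$time_grid))
      unlist(lapply(g$trace_ids, function(i) {
        tr <- prep$traces[[i]]
        pool <- observable_pool(traj, tr$map)[tr$grid_idx]
        stats::lm.fit(cbind(1, pool), tr$y)$residuals
      }))
    }), use.names = FALSE), silent = TRUE)
    # a rate set the integrator cannot handle is simply a terrible fit
    if (inherits(out, "try-error") || length(out) != n_resid || anyNA(out))
      rep(sqrt(total_ss / n_resid) * 1e3, n_resid)
    else out
  }

  # deterministic log-spaced multi-start around `start`
  p <- length(free)
  offsets <- matrix(0, nrow = n_starts, ncol = p)
  levels <- c(-1, -0.5, 0, 0.5, 1)
  for (s in seq_len(n_starts)) for (i in seq_len(p))
    offsets[s, i] <- levels[((s - 1) * p + (i - 1) * 3) %% 5 + 1]
  offsets[1, ] <- 0
  starts <- lapply(seq_len(n_starts),
                   function(s) log(start) + offsets[s, ] * log(10))

  check_identifiability(residual_fun, starts[[1]], free)

  ssr_of <- function(th) {
    r <- try(residual_fun(th), silent = TRUE)
    if (inherits(r, "try-error")) Inf else sum(r^2)
  }
  start_ssr <- vapply(starts, ssr_of, numeric(1))
  order_best <- order(start_ssr)[seq_len(min(refine_top, n_starts))]

  best <- NULL
  for (b in order_best) {
    if (!is.finite(start_ssr[b])) next
    fit <- try(minpack.lm::nls.lm(
      par = starts[[b]], fn = residual_fun,
      lower = rep(log(1e-4), p), upper = rep(log(1e5), p),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj) best <- list(fit = fit, obj = obj)
    if (best$obj < 1e-12 * total_ss) break
  }
  if (is.null(best))
    stop("global fit failed from every start", call. = FALSE)

  theta_hat <- best$fit$par
  rates_hat <- make_rates(theta_hat)
  net_hat <- suppressMessages(build_network(rates_hat, mode))

  amp_rows <- list()
  trace_rss <- numeric(length(prep$traces))
  for (g in prep$groups) {
    traj <- integrate_ensemble(net_hat, g$conditions, g$time_grid)
    for (i in g$trace_ids) {
      tr <- prep$traces[[i]]
      pool <- observable_pool(traj, tr$map)[tr$grid_idx]
      lf <- stats::lm.fit(cbind(1, pool), tr$y)
      cf <- lf$coefficients; cf[is.na(cf)] <- 0
      trace_rss[i] <- sum(lf$residuals^2)
      amp_rows[[i]] <- tibble::tibble(
        trace = i, channel = tr$channel,
        conc_70SIC = g$conditions$conc_70SIC, conc_TC = g$conditions$conc_TC,
        conc_EFG = g$conditions$conc_EFG,
        F0 = unname(cf[1]), amplitude = unname(cf[2]), rss = trace_rss[i])
    }
  }

  structure(list(
    rates = rates_hat, mode = mode, free = free,
    fixed = fixed,
    amplitudes = dplyr::bind_rows(amp_rows),
    objective = best$obj, trace_rss = trace_rss,
    converged = best$fit$info %in% 1:4,
    optimizer_info = best$fit$message,
    n_starts = n_starts, start_objectives = start_ssr,
    n_points = sum(vapply(prep$traces, function(tr) length(tr$y), numeric(1)))
  ), class = "global_fit")
}

check_identifiability <- function(residual_fun, theta, free, tol = 1e-8) {
  r0 <- residual_fun(theta)
  h <- 0.1  # ~10% rate perturbation on the log scale, well above solver noise
  J <- vapply(seq_along(theta), function(i) {
    th <- theta; th[i] <- th[i] + h
    (residual_fun(th) - r0) / h
  }, numeric(length(r0)))
  J <- matrix(J, ncol = length(theta))
  cn <- sqrt(colSums(J^2))
  scale0 <- max(cn, sqrt(sum(r0^2)), 1e-30)
  dead <- cn < 1e-5 * scale0
  if (any(dead))
    stop("structurally unidentifiable: the data carry no information about ",
         paste(free[dead], collapse = ", "),
         " (zero sensitivity in every trace); fix or drop these parameters",
         call. = FALSE)
  sv <- svd(sweep(J, 2, cn, "/"))$d
  if (min(sv) / max(sv) < tol)
    warning("weakly identifiable free-parameter combination (condition ",
            format(max(sv) / min(sv), digits = 3),
            "); expect wide confidence intervals", call. = FALSE)
  invisible(TRUE)
}

prepare_dataset <- function(ds) {
  traces <- vector("list", nrow(ds))
  key <- character(nrow(ds))
  conds <- list()
  for (i in seq_len(nrow(ds))) {
    d <- as.data.frame(ds$data[[i]])
    if (!all(c("time_s", "fluorescence_au") %in% names(d)))
      stop("trace ", i, " lacks time_s/fluorescence_au columns", call. = FALSE)
    cond <- reaction_conditions(
      conc_70SIC = ds$conc_70SIC[i], conc_TC = ds$conc_TC[i],
      conc_EFG = if ("conc_EFG" %in% names(ds)) ds$conc_EFG[i] else 0,
      temperature_scale = if ("temperature_scale" %in% names(ds))
        ds$temperature_scale[i] else 1)
    key[i] <- paste(cond$conc_70SIC, cond$conc_TC, cond$conc_EFG,
                    cond$temperature_scale, sep = "|")
    conds[[key[i]]] <- cond
    traces[[i]] <- list(channel = ds$channel[i],
                        map = observable_map(ds$channel[i]),
                        t = d$time_s, y = d$fluorescence_au)
  }
  groups <- lapply(unique(key), function(k) {
    ids <- which(key == k)
    grid <- sort(unique(unlist(lapply(ids, function(i) traces[[i]]$t))))
    if (grid[1] != 0) grid <- c(0, grid)
    for (i in ids)
      traces[[i]]$grid_idx <<- match(traces[[i]]$t, grid)
    list(conditions = conds[[k]], time_grid = grid, trace_ids = ids)
  })
  list(traces = traces, groups = groups)
}

#' Assemble a trace dataset tibble
#'
#' Normalizes the inputs of [global_fit()]: either a list of
#' `ensemble_trace` objects (conditions and channel read from attributes) or
#' an already-tabular dataset with one row per trace.
#'
#' @param x List of `ensemble_trace` objects, or a data frame with columns
#'   `channel`, `conc_70SIC`, `conc_TC` (optionally `conc_EFG`,
#'   `temperature_scale`, `noise_sigma`) and list-column `data`.
#' @return A tibble with one row per trace.
#' @export
as_trace_dataset <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("channel", "conc_70SIC", "conc_TC", "data") %in% names(x)))
      stop("dataset must have columns channel, conc_70SIC, conc_TC, data",
           call. = FALSE)
    return(tibble::as_tibble(x))
  }
  if (!is.list(x) || !length(x) || !all(vapply(x, inherits, logical(1), "ensemble_trace")))
    stop("`x` must be a dataset tibble or a list of ensemble_trace objects",
         call. = FALSE)
  dplyr::bind_rows(lapply(x, function(tr) {
    cond <- attr(tr, "conditions")
    if (is.null(cond)) stop("ensemble_trace lacks conditions metadata", call. = FALSE)
    tibble::tibble(channel = attr(tr, "channel"),
                   conc_70SIC = cond$conc_70SIC, conc_TC = cond$conc_TC,
                   conc_EFG = cond$conc_EFG,
                   temperature_scale = cond$temperature_scale,
                   noise_sigma = attr(tr, "noise_sigma") %||% 0,
                   data = list(tibble::tibble(time_s = tr$time_s,
                                              fluorescence_au = tr$fluorescence_au)))
  }))
}

#' @export
print.global_fit <- function(x, ...) {
  cat("<global_fit>", x$mode, "mode |", nrow(x$amplitudes), "traces,",
      x$n_points, "points | objective", format(x$objective, digits = 4), "\n")
  cat("  free: ", paste(x$free, collapse = ", "), "\n", sep = "")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  for (nm in c("k12", "k_m12", "k3", "k4", "k4A", "k_m4A"))
    if (nm %in% x$free)
      cat(sprintf("  %-6s = %.5g\n", nm, x$rates[[nm]]))
  if (all(c("k12", "k_m12") %in% x$free))
    cat(sprintf("  Kd(B)  = %.5g uM\n", x$rates$k_m12 / x$rates$k12))
  if (!x$converged) cat("  NOT converged:", x$optimizer_info, "\n")
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for a global fit
#'
#' Regenerates each trace from the fitted model plus Gaussian noise with the
#' trace's own residual standard deviation, refits, and summarizes the
#' spread of the re-estimated rates.  Seeded and deterministic.
#'
#' @param fit A `global_fit`.
#' @param dataset The dataset that produced it.
#' @param n_boot Number of bootstrap replicates (default 20).
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `parameter`, `estimate`, `se`, `lo`, `hi`
#'   (2.5/97.5 percentiles).
#' @export
global_fit_ci <- function(fit, dataset, n_boot = 20, seed) {
  stopifnot(inherits(fit, "global_fit"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  ds <- as_trace_dataset(dataset)
  prep <- prepare_dataset(ds)
  net <- suppressMessages(build_network(fit$rates, fit$mode))

  fitted_y <- vector("list", nrow(ds))
  sds <- numeric(nrow(ds))
  for (g in prep$groups) {
    traj <- integrate_ensemble(net, g$conditions, g$time_grid)
    for (i in g$trace_ids) {
      tr <- prep$traces[[i]]
      pool <- observable_pool(traj, tr$map)[tr$grid_idx]
      a <- fit$amplitudes[fit$amplitudes$trace == i, ]
      fitted_y[[i]] <- a$F0 + a$amplitude * pool
      res_sd <- stats::sd(tr$y - fitted_y[[i]])
      sds[i] <- max(res_sd, 1e-6 * diff(range(tr$y)))
    }
  }

  set.seed(seed)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = length(fit$free),
                  dimnames = list(NULL, fit$free))
  start_hat <- stats::setNames(
    vapply(fit$free, function(nm) fit$rates[[nm]], numeric(1)), fit$free)
  for (b in seq_len(n_boot)) {
    ds_b <- ds
    for (i in seq_len(nrow(ds)))
      ds_b$data[[i]] <- tibble::tibble(
        time_s = prep$traces[[i]]$t,
        fluorescence_au = fitted_y[[i]] + stats::rnorm(length(fitted_y[[i]]), 0, sds[i]))
    fb <- try(suppressWarnings(global_fit(
      ds_b, mode = fit$mode, free = fit$free, fixed = fit$fixed,
      start = start_hat, n_starts = 1, refine_top = 1)), silent = TRUE)
    if (!inherits(fb, "try-error"))
      boots[b, ] <- vapply(fit$free, function(nm) fb$rates[[nm]], numeric(1))
  }

  tibble::tibble(
    parameter = fit$free,
    estimate = unname(start_hat),
    se = apply(boots, 2, stats::sd, na.rm = TRUE),
    lo = apply(boots, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
    hi = apply(boots, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  )
}
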