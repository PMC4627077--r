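#' Fit a single-exponential time course
#'
#' Least-squares fit of `F(t) = F0 + F1 * exp(-k' t)` to a fluorescence
#' trace.  The sign of `F1` is free, so rising and falling traces are both
#' handled.  The rate enters nonlinearly; for each candidate rate the
#' amplitudes are solved by linear least squares (variable projection), and
#' the rate itself is found by deterministic multi-start over a log-spaced
#' grid followed by local refinement, so no random seed is involved.
#'
#' @param trace An `ensemble_trace` (or any data frame with columns `time_s`
#'   and `fluorescence_au`).
#' @param k_grid Log-spaced candidate rates for the multi-start
#'   (default `10^seq(-2, 3, length.out = 21)` s^-1).
#' @return An object of class `exp_fit` with fields `model = "mono"`, `F0`,
#'   `F1`, `k_prime`, `rss`, `converged`, `degenerate`, `warnings`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' tr <- tibble::tibble(time_s = t, fluorescence_au = 1 - 0.3 * exp(-5 * t))
#' fit_monoexponential(tr)
#' @export
fit_monoexponential <- function(trace, k_grid = 10^seq(-2, 3, length.out = 21)) {
  d <- check_trace_df(trace)
  t <- d$time_s; y <- d$fluorescence_au
  warnings <- character()
  if (length(t) < 10)
    warnings <- c(warnings, "fewer than 10 time points")

  yrange <- diff(range(y))
  if (yrange < 1e-12 * max(1, abs(mean(y)))) {
    return(new_exp_fit(model = "mono", F0 = mean(y), F1 = 0,
                       k_prime = NA_real_, rss = 0, converged = FALSE,
                       degenerate = TRUE,
                       warnings = c(warnings, "constant trace: rate unidentifiable")))
  }

  rss_of <- function(logk) mono_vp(t, y, exp(logk))$rss
  grid_rss <- vapply(log(k_grid), rss_of, numeric(1))
  lk0 <- log(k_grid)[which.min(grid_rss)]
  opt <- stats::optim(lk0, rss_of, method = "Brent",
                      lower = lk0 - log(100), upper = lk0 + log(100))
  k <- exp(opt$par)
  vp <- mono_vp(t, y, k)

  degenerate <- abs(vp$coef[2]) < 1e-8 * yrange
  if (degenerate)
    warnings <- c(warnings, "amplitude ~ 0: rate unidentifiable")
  if (!degenerate && max(t) < 2 / k)
    warnings <- c(warnings, sprintf(
      "trace spans %.3g s < 2/k' = %.3g s; rate poorly constrained",
      max(t), 2 / k))
  for (w in warnings) warning(w, call. = FALSE)

  new_exp_fit(model = "mono", F0 = vp$coef[1], F1 = vp$coef[2],
              k_prime = k, rss = vp$rss,
              converged = opt$convergence == 0 && !degenerate,
              degenerate = degenerate, warnings = warnings)
}

#' Fit a double-exponential time course
#'
#' Least-squares fit of
#' `F(t) = F0 + F1 * exp(-k1app t) + F2 * exp(-k2app t)`,
#' the form used for biphasic quench/recovery traces.  Amplitudes are
#' profiled out linearly (variable projection); the two rates are optimized
#' in the reparametrization `k1 = m*r`, `k2 = m/r` with `r = 1 + exp(w)`
#' (geometric-mean rate and separation), which keeps `k1 >= k2` by
#' construction and remains smooth as the rates coalesce.  Deterministic
#' multi-start over a log-spaced `(k1, k2)` grid.  Fits with rates within 5%
#' of each other are flagged degenerate.
#'
#' @param trace An `ensemble_trace` (or data frame with `time_s`,
#'   `fluorescence_au`).
#' @param k_grid Log-spaced candidate rates used to seed `(k1, k2)` pairs.
#' @return An `exp_fit` with `model = "bi"`, fields `F0`, `F1`, `F2`,
#'   `k1app >= k2app`, `rss`, `converged`, `degenerate`.
#' @examples
#' t <- seq(0, 1, by = 0.005)
#' y <- 1 - 0.5 * exp(-30 * t) + 0.4 * exp(-10 * t)
#' fit_biexponential(tibble::tibble(time_s = t, fluorescence_au = y))
#' @export
fit_biexponential <- function(trace, k_grid = 10^seq(-1, 3, length.out = 9)) {
  d <- check_trace_df(trace)
  t <- d$time_s; y <- d$fluorescence_au
  warnings <- character()
  if (length(t) < 10) warnings <- c(warnings, "fewer than 10 time points")

  yrange <- diff(range(y))
  if (yrange < 1e-12 * max(1, abs(mean(y)))) {
    return(new_exp_fit(model = "bi", F0 = mean(y), F1 = 0, F2 = 0,
                       k1app = NA_real_, k2app = NA_real_, rss = 0,
                       converged = FALSE, degenerate = TRUE,
                       warnings = c(warnings, "constant trace: rates unidentifiable")))
  }

  # theta = (log m, w): k1 = m * r, k2 = m / r, r = 1 + exp(w)
  theta_rates <- function(th) {
    r <- 1 + exp(th[2])
    c(exp(th[1]) * r, exp(th[1]) / r)
  }
  rss_of <- function(th) {
    ks <- theta_rates(th)
    bi_vp(t, y, ks[1], ks[2])$rss
  }

  starts <- list()
  for (i in seq_along(k_grid)) for (j in seq_along(k_grid)) {
    if (k_grid[i] > k_grid[j])
      starts[[length(starts) + 1L]] <-
        c(log(sqrt(k_grid[i] * k_grid[j])),
          log(sqrt(k_grid[i] / k_grid[j]) - 1 + 1e-9))
  }
  start_rss <- vapply(starts, rss_of, numeric(1))
  best <- order(start_rss)[seq_len(min(3L, length(starts)))]

  opt_best <- NULL
  for (b in best) {
    op <- stats::optim(starts[[b]], rss_of, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(opt_best) || op$value < opt_best$value) opt_best <- op
  }
  ks <- theta_rates(opt_best$par)
  vp <- bi_vp(t, y, ks[1], ks[2])

  degenerate <- (ks[1] - ks[2]) / ks[1] < 0.05
  if (degenerate)
    warnings <- c(warnings, "k1app and k2app within 5%: biexponential degenerate")
  for (w in warnings) warning(w, call. = FALSE)

  new_exp_fit(model = "bi", F0 = vp$coef[1], F1 = vp$coef[2], F2 = vp$coef[3],
              k1app = ks[1], k2app = ks[2], rss = vp$rss,
              converged = opt_best$convergence == 0 && !degenerate,
              degenerate = degenerate, warnings = warnings)
}

#' Overall rate from the two apparent rate constants
#'
#' Harmonic composition `k_ov = k1app * k2app / (k1app + k2app)`, the
#' effective rate of completing both phases of a biphasic process in series.
#' Symmetric in its arguments and bounded above by the smaller of the two.
#'
#' @param k1app,k2app Apparent rate constants (s^-1, both > 0).
#' @return `k_ov` in s^-1.
#' @examples
#' overall_rate(40, 10)  # 8
#' @export
overall_rate <- function(k1app, k2app) {
  if (!is.numeric(k1app) || !is.numeric(k2app) ||
      any(!is.finite(c(k1app, k2app)) & !is.infinite(c(k1app, k2app))) ||
      any(c(k1app, k2app) <= 0))
    stop("`k1app` and `k2app` must be positive", call. = FALSE)
  ifelse(is.infinite(k1app), k2app,
         ifelse(is.infinite(k2app), k1app,
                k1app * k2app / (k1app + k2app)))
}

# ---- internals ----

check_trace_df <- function(trace) {
  d <- as.data.frame(trace)
  if (!all(c("time_s", "fluorescence_au") %in% names(d)))
    stop("trace must have columns `time_s` and `fluorescence_au`", call. = FALSE)
  if (anyNA(d$time_s) || anyNA(d$fluorescence_au))
    stop("trace contains missing values", call. = FALSE)
  d[order(d$time_s), c("time_s", "fluorescence_au")]
}

# linear solve of F0 + F1 e^{-kt}; returns coef and rss
mono_vp <- function(t, y, k) {
  X <- cbind(1, exp(-k * t))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = unname(cf), rss = sum(fit$residuals^2))
}

bi_vp <- function(t, y, k1, k2) {
  X <- cbind(1, exp(-k1 * t), exp(-k2 * t))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = unname(cf), rss = sum(fit$residuals^2))
}

new_exp_fit <- function(model, F0, F1, F2 = NA_real_, k_prime = NA_real_,
                        k1app = NA_real_, k2app = NA_real_, rss, converged,
                        degenerate, warnings = character()) {
  structure(list(model = model, F0 = F0, F1 = F1, F2 = F2,
                 k_prime = k_prime, k1app = k1app, k2app = k2app,
                 rss = rss, converged = converged, degenerate = degenerate,
                 warnings = warnings),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "mono") {
    cat(sprintf("<exp_fit mono> F0 = %.5g, F1 = %.5g, k' = %.5g s^-1, rss = %.3g\n",
                x$F0, x$F1, x$k_prime, x$rss))
  } else {
    cat(sprintf(
      "<exp_fit bi> F0 = %.5g, F1 = %.5g, F2 = %.5g, k1app = %.5g, k2app = %.5g s^-1, rss = %.3g\n",
      x$F0, x$F1, x$F2, x$k1app, x$k2app, x$rss))
  }
  if (!x$converged) cat("  NOT converged\n")
  if (x$degenerate) cat("  DEGENERATE fit\n")
  invisible(x)
}
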