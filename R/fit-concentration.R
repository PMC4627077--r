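#' Linear concentration dependence of the fast apparent rate
#'
#' Ordinary least squares of `rate ~ concentration`.  For a reversible
#' bimolecular binding step observed under pseudo-first-order conditions the
#' fast apparent rate rises linearly with the varied concentration: the
#' slope estimates the association rate constant `k12` and the intercept
#' estimates the off-rate `k_m12` (strictly, the intercept also carries a
#' contribution from the downstream conversion rate `k3` when the following
#' step is not much slower).
#'
#' @param data Data frame with columns `concentration` (uM) and `rate`
#'   (s^-1); at least 3 distinct concentrations.
#' @return Object of class `conc_fit`: `slope` (s^-1 uM^-1), `intercept`
#'   (s^-1), standard errors, residuals and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(concentration = seq(0.2, 1.2, by = 0.2),
#'                     rate = 36 * seq(0.2, 1.2, by = 0.2) + 5)
#' fit_linear_concentration(d)
#' @export
fit_linear_concentration <- function(data) {
  d <- as.data.frame(data)
  if (!all(c("concentration", "rate") %in% names(d)))
    stop("`data` must have columns `concentration` and `rate`", call. = FALSE)
  if (nrow(d) < 3)
    stop("at least 3 concentration points are required", call. = FALSE)
  if (length(unique(d$concentration)) < 2)
    stop("all concentrations identical: slope is not estimable", call. = FALSE)
  fit <- stats::lm(rate ~ concentration, data = d)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = sm["concentration", "Std. Error"],
                 intercept_se = sm["(Intercept)", "Std. Error"],
                 residuals = stats::residuals(fit),
                 fit = fit),
            class = "conc_fit")
}

#' @export
print.conc_fit <- function(x, ...) {
  cat(sprintf("<conc_fit linear> slope = %.5g +- %.2g s^-1 uM^-1, intercept = %.5g +- %.2g s^-1\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Michaelis-Menten concentration dependence of an apparent rate
#'
#' Nonlinear least squares of `rate = Vmax * S / (KM + S)` against
#' concentration `S`, the saturating form observed when binding
#' pre-equilibrates before a rate-limiting conversion.  Initialized at
#' `Vmax = max(rate)`, `KM = median(S)` and solved with a
#' Levenberg-Marquardt trust-region optimizer.
#'
#' @param data Data frame with columns `concentration` (uM) and `rate`
#'   (s^-1); at least 4 points.
#' @return Object of class `mm_fit`: `Vmax`, `KM`, standard errors,
#'   residuals, `converged`, `degenerate` (KM driven to the zero boundary,
#'   as happens when all rates are equal) and the underlying `nls` object.
#' @examples
#' S <- c(0.2, 0.4, 0.6, 0.9, 1.2)
#' fit_michaelis_menten(tibble::tibble(concentration = S,
#'                                     rate = 11 * S / (0.56 + S)))
#' @export
fit_michaelis_menten <- function(data) {
  d <- as.data.frame(data)
  if (!all(c("concentration", "rate") %in% names(d)))
    stop("`data` must have columns `concentration` and `rate`", call. = FALSE)
  if (nrow(d) < 4)
    stop("at least 4 points are required", call. = FALSE)

  start <- list(Vmax = max(d$rate), KM = stats::median(d$concentration))
  fit <- try(minpack.lm::nlsLM(
    rate ~ Vmax * concentration / (KM + concentration),
    data = d, start = start,
    lower = c(Vmax = 0, KM = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  ), silent = TRUE)

  if (inherits(fit, "try-error")) {
    warning("Michaelis-Menten fit did not converge", call. = FALSE)
    return(structure(list(Vmax = NA_real_, KM = NA_real_,
                          Vmax_se = NA_real_, KM_se = NA_real_,
                          residuals = rep(NA_real_, nrow(d)),
                          converged = FALSE, degenerate = TRUE, fit = NULL),
                     class = "mm_fit"))
  }

  cf <- stats::coef(fit)
  sm <- try(summary(fit)$coefficients, silent = TRUE)
  se <- if (inherits(sm, "try-error")) c(NA_real_, NA_real_) else sm[, "Std. Error"]
  degenerate <- cf[["KM"]] < 1e-6 * max(d$concentration)
  if (degenerate)
    warning("KM at the zero boundary: rates show no concentration dependence",
            call. = FALSE)
  structure(list(Vmax = cf[["Vmax"]], KM = cf[["KM"]],
                 Vmax_se = unname(se[1]), KM_se = unname(se[2]),
                 residuals = stats::residuals(fit),
                 converged = fit$convInfo$isConv %||% TRUE,
                 degenerate = degenerate, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Vmax = %.5g +- %.2g s^-1, KM = %.5g +- %.2g uM\n",
              x$Vmax, x$Vmax_se, x$KM, x$KM_se))
  if (x$degenerate) cat("  DEGENERATE (KM at boundary)\n")
  invisible(x)
}
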