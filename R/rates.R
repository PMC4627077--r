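#' Microscopic rate constants of the TC / 70SIC reaction scheme
#'
#' Container for the rate constants of the branched kinetic scheme describing
#' ternary complex (TC = aa-tRNA.EF-Tu.GTP) interaction with the 70S
#' initiation complex (70SIC).  The scheme lumps initial binding and
#' codon-recognition/GTP-hydrolysis into a single reversible step forming
#' Complex B, followed by an essentially simultaneous Pi-release /
#' accommodation / EF-Tu-L11-separation step forming Complex C, from which
#' EF-Tu.GDP leaves the ribosome.  In the full model Complex C is a branch
#' point: EF-Tu can exit irreversibly as EF-Tu.GDP (concomitant with its
#' large conformational change) or reversibly as the metastable, GTP-like
#' EF-Tu.GDP* species.
#'
#' Units are fixed package-wide: time in s, concentration in uM, so
#' first-order rates are s^-1 and bimolecular rates s^-1 uM^-1.
#'
#' @param k12 Second-order association rate constant forming Complex B
#'   (s^-1 uM^-1).
#' @param k_m12 First-order dissociation rate of Complex B (s^-1).
#' @param k3 Complex B -> Complex C rate (Pi release / accommodation /
#'   EF-Tu-L11 separation; s^-1).
#' @param k4 Irreversible EF-Tu.GDP exit rate from Complex C (s^-1).
#' @param k4A Reversible EF-Tu.GDP* exit rate from Complex C (s^-1; full
#'   model only, default 0).
#' @param k_m4A Rebinding rate of EF-Tu.GDP* to the EF-Tu-free PRE complex
#'   (s^-1 uM^-1; full model only).  `NA` (the default) means "not
#'   specified": when a full-mode network is built with `k4A > 0` it is
#'   defaulted to `k12` with a message, since no independent estimate exists.
#' @param k_efg Capture rate of the PRE complex by EF-G.GTP (s^-1 uM^-1,
#'   default 0; the captured POST state cannot rebind EF-Tu.GDP*).
#' @param k_conv Solution-phase conversion rate EF-Tu.GDP* -> EF-Tu.GDP
#'   (s^-1, default 0; the GDP* species need only persist transiently).
#'
#' @return An object of class `rate_constants` (a named list).
#' @examples
#' rate_constants(k12 = 36, k_m12 = 3.6, k3 = 15.4, k4 = 19.6)
#' @export
rate_constants <- function(k12, k_m12, k3, k4,
                           k4A = 0, k_m4A = NA_real_,
                           k_efg = 0, k_conv = 0) {
  rc <- list(k12 = k12, k_m12 = k_m12, k3 = k3, k4 = k4,
             k4A = k4A, k_m4A = k_m4A, k_efg = k_efg, k_conv = k_conv)
  for (nm in names(rc)) {
    v <- rc[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop("rate constant `", nm, "` must be a single number", call. = FALSE)
    if (nm != "k_m4A" && (is.na(v) || v < 0))
      stop("rate constant `", nm, "` must be finite and >= 0 (got ", v, ")",
           call. = FALSE)
    if (nm == "k_m4A" && !is.na(v) && v < 0)
      stop("rate constant `k_m4A` must be >= 0 (got ", v, ")", call. = FALSE)
  }
  structure(rc, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants>  (s^-1, bimolecular s^-1 uM^-1)\n")
  vals <- vapply(unclass(x), function(v) format(v, digits = 4), character(1))
  cat(paste0("  ", format(names(vals), width = 6), " = ", vals), sep = "\n")
  if (x$k12 > 0)
    cat("  Kd(B) = k_m12/k12 =", format(x$k_m12 / x$k12, digits = 4), "uM\n")
  invisible(x)
}

#' Equilibrium dissociation constant of Complex B
#'
#' `k_m12 / k12`, the concentration at which half the fast-binding step is
#' reversed (uM).
#'
#' @param rates A [rate_constants()] object.
#' @return Kd in uM.
#' @export
kd_complex_b <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (rates$k12 <= 0) stop("Kd undefined: k12 = 0", call. = FALSE)
  rates$k_m12 / rates$k12
}

#' Uniformly rescale all rate constants
#'
#' Applies a dimensionless multiplier to every rate constant, the device used
#' to emulate a temperature change (0.5 approximates moving from 25 to 21
#' degrees C, where single-molecule dwell times are about 2-fold longer).
#'
#' @param rates A [rate_constants()] object.
#' @param factor Positive multiplier.
#' @return A rescaled `rate_constants` object.
#' @export
scale_rates <- function(rates, factor) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 0)
    stop("`factor` must be a single positive number", call. = FALSE)
  out <- lapply(unclass(rates), function(v) v * factor)
  structure(out, class = "rate_constants")
}

#' Reaction conditions for a mixing experiment
#'
#' @param conc_70SIC 70S initiation complex concentration after mixing (uM).
#' @param conc_TC Ternary complex concentration after mixing (uM).
#' @param conc_EFG EF-G.GTP concentration (uM, default 0).  Treated as
#'   constant (catalytic excess) during integration.
#' @param temperature_scale Dimensionless multiplier applied uniformly to all
#'   rate constants before integration/simulation (default 1; 0.5 emulates
#'   21 degrees C relative to the 25 degrees C ensemble reference).
#'
#' @return An object of class `reaction_conditions`.
#' @examples
#' reaction_conditions(conc_70SIC = 0.1, conc_TC = 0.6)
#' @export
reaction_conditions <- function(conc_70SIC, conc_TC, conc_EFG = 0,
                                temperature_scale = 1) {
  cc <- list(conc_70SIC = conc_70SIC, conc_TC = conc_TC,
             conc_EFG = conc_EFG, temperature_scale = temperature_scale)
  for (nm in names(cc)) {
    v <- cc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (cc$conc_70SIC < 0 || cc$conc_TC < 0 || cc$conc_EFG < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (cc$temperature_scale <= 0)
    stop("`temperature_scale` must be > 0", call. = FALSE)
  structure(cc, class = "reaction_conditions")
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat("<reaction_conditions> 70SIC", x$conc_70SIC, "uM; TC", x$conc_TC,
      "uM; EF-G", x$conc_EFG, "uM; temperature_scale", x$temperature_scale, "\n")
  invisible(x)
}
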