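#' Fluorescence observable definitions
#'
#' Maps species trajectories onto the four stopped-flow reporter channels as
#' affine combinations `F(t) = F0 + amplitude * sum(weights * species)`:
#'
#' * `L11_Cy3` — Cy3 on ribosomal protein L11 quenched by the acceptor/
#'   quencher on EF-Tu while EF-Tu sits against the GTPase-associated center,
#'   i.e. in Complex B only; the signal dips as B forms and recovers as B
#'   converts to C (biphasic). Weights: `B`. Default amplitude negative.
#' * `tRNA_Cy3` — Cy3 on the tRNA D-loop quenched by the label on EF-Tu.
#'   Both labels travel inside the ternary complex, so free TC, Complex B
#'   and Complex C are all quenched (FRET persists through accommodation);
#'   fluorescence is recovered only when EF-Tu fully dissociates.  The
#'   rising signal is therefore proportional to the EF-Tu-departed ribosome
#'   pool `PRE + POST`. Default amplitude positive.
#' * `prf` — proflavin on P-site fMet-tRNA, decreasing in proportion to the
#'   accommodated pool `C + PRE + POST`. Default amplitude negative.
#' * `PBP` — coumarin-labeled phosphate-binding protein, increasing with
#'   cumulative inorganic phosphate released.  Pi release is stoichiometric
#'   with the irreversible B -> C transition, so cumulative Pi equals
#'   `C + PRE + POST` exactly; PBP binding is treated as instantaneous
#'   (C-PBP premixed in excess). Default amplitude positive.
#'
#' @param channel One of `"L11_Cy3"`, `"tRNA_Cy3"`, `"prf"`, `"PBP"`.
#' @param F0 Baseline fluorescence (a.u., default 1).
#' @param amplitude Fluorescence change per uM of the weighted species pool
#'   (a.u./uM).  Defaults to -2 for quench/decrease channels (L11_Cy3, prf)
#'   and +2 for recovery/increase channels (tRNA_Cy3, PBP).
#' @return An object of class `observable_map`.
#' @export
observable_map <- function(channel = c("L11_Cy3", "tRNA_Cy3", "prf", "PBP"),
                           F0 = 1, amplitude = NULL) {
  channel <- match.arg(channel)
  weights <- switch(channel,
    L11_Cy3  = c(B = 1),
    tRNA_Cy3 = c(PRE = 1, POST = 1),
    prf      = c(C = 1, PRE = 1, POST = 1),
    PBP      = c(C = 1, PRE = 1, POST = 1)
  )
  if (is.null(amplitude))
    amplitude <- switch(channel, L11_Cy3 = -2, prf = -2, tRNA_Cy3 = 2, PBP = 2)
  stopifnot(is.numeric(F0), length(F0) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  structure(list(channel = channel, F0 = F0, amplitude = amplitude,
                 weights = weights),
            class = "observable_map")
}

#' Observable channel names
#' @return Character vector of the four supported channels.
#' @export
observable_channels <- function() c("L11_Cy3", "tRNA_Cy3", "prf", "PBP")

#' Species pool seen by an observable
#'
#' The weighted species combination (uM) underlying a channel, before the
#' affine fluorescence transform.  Used internally by the fitters.
#'
#' @param traj A `species_trajectory`.
#' @param map An [observable_map()] (or channel name).
#' @return Numeric vector, one value per time point.
#' @export
observable_pool <- function(traj, map) {
  if (is.character(map)) map <- observable_map(map)
  stopifnot(inherits(traj, "species_trajectory"), inherits(map, "observable_map"))
  cols <- intersect(names(map$weights), names(traj))
  if (!length(cols)) return(rep(0, nrow(traj)))
  as.vector(as.matrix(traj[cols]) %*% map$weights[cols])
}

#' Project a species trajectory onto a fluorescence channel
#'
#' @param traj A `species_trajectory` from [integrate_ensemble()].
#' @param map An [observable_map()], or a channel name (default map used).
#' @return A tibble of class `ensemble_trace` with columns `time_s`,
#'   `fluorescence_au`; channel, conditions and `noise_sigma = 0` attached
#'   as attributes.
#' @examples
#' net <- build_network(rate_constants(36, 3.6, 15.4, 19.6))
#' traj <- integrate_ensemble(net, reaction_conditions(0.1, 0.5),
#'                            seq(0, 1, by = 0.005))
#' tr <- project_observable(traj, "L11_Cy3")
#' @export
project_observable <- function(traj, map) {
  if (is.character(map)) map <- observable_map(map)
  stopifnot(inherits(map, "observable_map"))
  pool <- observable_pool(traj, map)
  new_ensemble_trace(
    time_s = traj$time_s,
    fluorescence_au = map$F0 + map$amplitude * pool,
    channel = map$channel,
    conditions = attr(traj, "conditions"),
    noise_sigma = 0
  )
}

new_ensemble_trace <- function(time_s, fluorescence_au, channel, conditions,
                               noise_sigma = 0, seed = NA_integer_) {
  stopifnot(length(time_s) == length(fluorescence_au))
  out <- tibble::tibble(time_s = time_s, fluorescence_au = fluorescence_au)
  attr(out, "channel") <- channel
  attr(out, "conditions") <- conditions
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "seed") <- seed
  class(out) <- c("ensemble_trace", class(out))
  out
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat("<ensemble_trace> channel", attr(x, "channel"),
      "|", nrow(x), "points, t in [", min(x$time_s), ",", max(x$time_s), "] s",
      "| noise_sigma", attr(x, "noise_sigma"), "\n")
  if (!is.null(cond))
    cat("  70SIC", cond$conc_70SIC, "uM; TC", cond$conc_TC, "uM; EF-G",
        cond$conc_EFG, "uM\n")
  NextMethod()
}
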