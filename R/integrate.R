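#' Integrate the deterministic mass-action kinetics of a network
#'
#' Solves the ordinary differential equations of a [build_network()] scheme
#' with a stiff-capable integrator (deSolve::lsoda, rtol 1e-8 / atol 1e-12)
#' from the mixing initial condition `R = conc_70SIC`, `T = conc_TC`, all
#' intermediates zero.  All rate constants are multiplied by
#' `conditions$temperature_scale` before integration; EF-G capture runs at
#' the pseudo-first-order rate `k_efg * conc_EFG`.
#'
#' @param network A `reaction_network` from [build_network()].
#' @param conditions A [reaction_conditions()] object.
#' @param time_grid Strictly increasing numeric vector of output times (s)
#'   starting at 0.
#' @return A tibble of class `species_trajectory`: column `time_s` plus one
#'   column per species (uM).  Conditions and network are attached as
#'   attributes `conditions` and `network`.
#' @examples
#' net <- build_network(rate_constants(36, 3.6, 15.4, 19.6))
#' traj <- integrate_ensemble(net, reaction_conditions(0.1, 0.6),
#'                            seq(0, 1, by = 0.01))
#' @export
integrate_ensemble <- function(network, conditions, time_grid) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(conditions, "reaction_conditions"))
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L || time_grid[1] != 0 ||
      any(diff(time_grid) <= 0))
    stop("`time_grid` must be strictly increasing and start at 0", call. = FALSE)

  species <- network$species
  ts <- conditions$temperature_scale

  # Pre-compute stoichiometry: for each reaction the effective scaled rate,
  # reactant indices (with order) and the net stoichiometric change vector.
  nr <- length(network$reactions)
  rate_eff <- numeric(nr)
  reactant_idx <- vector("list", nr)
  delta <- matrix(0, nrow = length(species), ncol = nr,
                  dimnames = list(species, NULL))
  for (j in seq_len(nr)) {
    r <- network$reactions[[j]]
    k <- r$rate * ts
    if (r$bimolecular_efg) k <- k * conditions$conc_EFG
    rate_eff[j] <- k
    reactant_idx[[j]] <- rep(match(names(r$reactants), species), r$reactants)
    for (s in names(r$reactants)) delta[s, j] <- delta[s, j] - r$reactants[[s]]
    for (s in names(r$products))  delta[s, j] <- delta[s, j] + r$products[[s]]
  }

  deriv <- function(t, y, parms) {
    flux <- rate_eff
    for (j in seq_len(nr))
      flux[j] <- flux[j] * prod(y[reactant_idx[[j]]])
    list(as.vector(delta %*% flux))
  }

  y0 <- stats::setNames(numeric(length(species)), species)
  y0["R"] <- conditions$conc_70SIC
  y0["T"] <- conditions$conc_TC

  sol <- try(deSolve::lsoda(y = y0, times = time_grid, func = deriv,
                            parms = NULL, rtol = 1e-8, atol = 1e-12),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(time_grid)) {
    stop("ODE integration failed for conditions: 70SIC = ",
         conditions$conc_70SIC, " uM, TC = ", conditions$conc_TC,
         " uM, EF-G = ", conditions$conc_EFG,
         " uM, temperature_scale = ", conditions$temperature_scale,
         call. = FALSE)
  }

  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_s"
  attr(out, "conditions") <- conditions
  attr(out, "network") <- network
  class(out) <- c("species_trajectory", class(out))
  out
}

#' Conservation residuals of a species trajectory
#'
#' Returns, per time point, the deviation of the ribosome pool
#' (R + B + C + PRE + POST) from `conc_70SIC` and of the EF-Tu pool
#' (T + B + C + Tu_star + Tu_gdp) from `conc_TC`.  Both should be below
#' 1e-6 uM in magnitude for a healthy integration.
#'
#' @param traj A `species_trajectory`.
#' @return A tibble with columns `time_s`, `ribosome_error`, `eftu_error` (uM).
#' @export
conservation_error <- function(traj) {
  stopifnot(inherits(traj, "species_trajectory"))
  cond <- attr(traj, "conditions")
  pool <- function(cols) {
    cols <- intersect(cols, names(traj))
    if (!length(cols)) return(rep(0, nrow(traj)))
    rowSums(as.matrix(traj[cols]))
  }
  tibble::tibble(
    time_s = traj$time_s,
    ribosome_error = pool(c("R", "B", "C", "PRE", "POST")) - cond$conc_70SIC,
    eftu_error = pool(c("T", "B", "C", "Tu_star", "Tu_gdp")) - cond$conc_TC
  )
}
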