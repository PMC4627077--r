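#' Build the mass-action reaction network for the scheme
#'
#' Assembles the species list and elementary mass-action reactions of the
#' TC + 70SIC scheme.  Species: `R` (free 70SIC), `T` (free TC), `B`
#' (Complex B, codon-recognized/GTP-hydrolyzed), `C` (Complex C,
#' accommodated with EF-Tu.GDP* still bound), `PRE` (pretranslocation
#' complex lacking EF-Tu), `Tu_gdp` (free EF-Tu.GDP), and, in full mode,
#' `Tu_star` (free metastable EF-Tu.GDP*); `POST` appears when EF-G capture
#' is enabled.
#'
#' In collapsed mode the branch through EF-Tu.GDP* is absent and the network
#' is the 4-reaction chain
#' `R + T -> B`, `B -> R + T`, `B -> C`, `C -> PRE + Tu_gdp`
#' (the first two steps of the mechanism, initial binding and codon
#' recognition/GTP hydrolysis, are lumped into the single reversible
#' k12/k_m12 step because the stopped-flow data do not resolve them).  Full
#' mode adds the reversible Complex C branch `C <-> PRE + Tu_star`
#' (k4A / k_m4A) and, if `k_conv > 0`, `Tu_star -> Tu_gdp` in solution.
#' If `k_efg > 0`, `PRE -> POST` captures the PRE complex with
#' pseudo-first-order rate `k_efg * conc_EFG` (EF-G held constant); POST
#' cannot rebind EF-Tu.GDP*.
#'
#' @param rates A [rate_constants()] object.
#' @param mode `"collapsed"` (default) or `"full"`.
#' @return An object of class `reaction_network`: list with `species`,
#'   `reactions` (each a list with `name`, `rate`, `reactants`, `products`,
#'   and `bimolecular_efg` flag), `mode` and `rates`.
#' @examples
#' net <- build_network(rate_constants(36, 3.6, 15.4, 19.6))
#' length(net$reactions)  # 4
#' @export
build_network <- function(rates, mode = c("collapsed", "full")) {
  stopifnot(inherits(rates, "rate_constants"))
  mode <- match.arg(mode)

  if (mode == "collapsed") {
    bad <- c(
      if (isTRUE(rates$k4A > 0)) "k4A",
      if (isTRUE(!is.na(rates$k_m4A) && rates$k_m4A > 0)) "k_m4A",
      if (isTRUE(rates$k_conv > 0)) "k_conv"
    )
    if (length(bad))
      stop("full-model rate(s) supplied in collapsed mode: ",
           paste(bad, collapse = ", "),
           " (use mode = \"full\")", call. = FALSE)
  }

  k_m4A <- rates$k_m4A
  if (mode == "full" && rates$k4A > 0 && is.na(k_m4A)) {
    k_m4A <- rates$k12
    message("k_m4A not specified; defaulting to k12 = ", rates$k12,
            " s^-1 uM^-1 (no independent estimate exists)")
  }
  if (is.na(k_m4A)) k_m4A <- 0

  rxn <- function(name, rate, reactants, products, efg = FALSE)
    list(name = name, rate = rate, reactants = reactants, products = products,
         bimolecular_efg = efg)

  reactions <- list(
    rxn("binding",      rates$k12,   c(R = 1, T = 1), c(B = 1)),
    rxn("unbinding",    rates$k_m12, c(B = 1),        c(R = 1, T = 1)),
    rxn("accommodation", rates$k3,   c(B = 1),        c(C = 1)),
    rxn("exit_gdp",     rates$k4,    c(C = 1),        c(PRE = 1, Tu_gdp = 1))
  )
  species <- c("R", "T", "B", "C", "PRE", "Tu_gdp")

  if (mode == "full") {
    species <- c(species, "Tu_star")
    reactions <- c(reactions, list(
      rxn("exit_gdpstar",   rates$k4A, c(C = 1), c(PRE = 1, Tu_star = 1)),
      rxn("rebind_gdpstar", k_m4A,     c(PRE = 1, Tu_star = 1), c(C = 1))
    ))
    if (rates$k_conv > 0)
      reactions <- c(reactions, list(
        rxn("gdpstar_decay", rates$k_conv, c(Tu_star = 1), c(Tu_gdp = 1))
      ))
  }

  if (rates$k_efg > 0) {
    species <- c(species, "POST")
    # EF-G is held at its nominal concentration (catalytic excess); the
    # effective first-order rate k_efg * conc_EFG is formed at integration.
    reactions <- c(reactions, list(
      rxn("efg_capture", rates$k_efg, c(PRE = 1), c(POST = 1), efg = TRUE)
    ))
  }

  structure(
    list(species = species, reactions = reactions, mode = mode, rates = rates),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> mode =", x$mode, "|", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    lhs <- paste(names(r$reactants), collapse = " + ")
    if (r$bimolecular_efg) lhs <- paste(lhs, "+ EFG")
    rhs <- paste(names(r$products), collapse = " + ")
    cat(sprintf("  %-14s %s -> %s  (k = %g)\n", r$name, lhs, rhs, r$rate))
  }
  invisible(x)
}
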