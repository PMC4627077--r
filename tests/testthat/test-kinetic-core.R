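test_that("network assembly matches the scheme in both modes", {
  net <- build_network(row1(), mode = "collapsed")
  expect_length(net$reactions, 4)
  expect_length(net$species, 6)
  expect_setequal(net$species, c("R", "T", "B", "C", "PRE", "Tu_gdp"))

  full <- rate_constants(100, 120, 19.9, 19.6, k4A = 19.6, k_m4A = 100,
                         k_efg = 2)
  netf <- build_network(full, mode = "full")
  expect_length(netf$reactions, 7)
  expect_true(all(c("Tu_star", "POST") %in% netf$species))
  # POST is never a reactant of the GDP* rebinding step
  rebind <- netf$reactions[[which(vapply(netf$reactions, `[[`, "", "name") ==
                                    "rebind_gdpstar")]]
  expect_false("POST" %in% names(rebind$reactants))
})

test_that("mode/rate validation refuses inconsistent configurations", {
  expect_error(build_network(rate_constants(36, 3.6, 15.4, 19.6, k4A = 5),
                             mode = "collapsed"), "full-model")
  expect_error(rate_constants(-1, 3.6, 15.4, 19.6), "k12")
  expect_error(reaction_conditions(-0.1, 0.5), ">= 0")
  expect_error(reaction_conditions(0.1, 0.5, temperature_scale = 0), "> 0")
})

test_that("no entry flux when k12 = 0", {
  net <- build_network(rate_constants(0, 3.6, 15.4, 19.6))
  traj <- integrate_ensemble(net, reaction_conditions(0.1, 1.0),
                             seq(0, 1, by = 0.01))
  expect_lt(max(traj$B, traj$C, traj$PRE), 1e-12)
  expect_equal(traj$R, rep(0.1, nrow(traj)), tolerance = 1e-10)
})

test_that("ribosome and EF-Tu pools are conserved to 1e-6 uM for varied inputs", {
  set.seed(11)
  for (i in 1:5) {
    k <- 10^stats::runif(6, -1, 2)
    full <- i %% 2 == 0
    rates <- if (full)
      rate_constants(k[1], k[2], k[3], k[4], k4A = k[5], k_m4A = k[6],
                     k_efg = 1)
    else rate_constants(k[1], k[2], k[3], k[4])
    net <- build_network(rates, mode = if (full) "full" else "collapsed")
    cond <- reaction_conditions(stats::runif(1, 0.05, 0.5),
                                stats::runif(1, 0.05, 1.2),
                                conc_EFG = if (full) 1 else 0,
                                temperature_scale = sample(c(0.5, 1), 1))
    traj <- integrate_ensemble(net, cond, fast_grid())
    ce <- conservation_error(traj)
    expect_lt(max(abs(ce$ribosome_error)), 1e-6)
    expect_lt(max(abs(ce$eftu_error)), 1e-6)
    expect_gt(min(as.matrix(traj[-1])), -1e-9)
  }
})

test_that("irreversible binding follows the second-order closed form", {
  k <- 5
  net <- build_network(rate_constants(k, 0, 0, 0))
  tg <- seq(0, 2, by = 0.02)
  # unequal pools
  traj <- integrate_ensemble(net, reaction_conditions(0.3, 0.8), tg)
  expect_equal(traj$B, second_order_B(k, 0.3, 0.8, tg), tolerance = 1e-7)
  # pseudo-first-order limit: B ~ R0 (1 - exp(-k12 T0 t)); the approximation
  # itself is good to ~R0/T0, i.e. ~1e-6 uM absolute here
  traj2 <- integrate_ensemble(net, reaction_conditions(0.001, 1.0), tg)
  expect_lt(max(abs(traj2$B - 0.001 * (1 - exp(-k * 1.0 * tg)))), 2e-6)
})

test_that("ODE solution matches the matrix-exponential oracle in the
           pseudo-first-order limit", {
  skip_if_not_installed("Matrix")
  tg <- seq(0, 1, by = 0.01)
  cond <- reaction_conditions(0.001, 1.0)
  traj <- integrate_ensemble(build_network(row1()), cond, tg)
  oracle <- expm_chain(row1(), 0.001, 1.0, tg)
  err <- max(abs(as.matrix(traj[, colnames(oracle)]) - oracle))
  expect_lt(err, 1e-6)
})

test_that("increasing EF-G capture monotonically suppresses Complex C", {
  rates <- rate_constants(100, 120, 19.9, 19.6, k4A = 19.6, k_m4A = 100,
                          k_efg = 2)
  tg <- fast_grid()
  peaks <- vapply(c(0, 0.5, 1, 2, 4), function(efg) {
    traj <- integrate_ensemble(build_network(rates, "full"),
                               reaction_conditions(0.4, 0.1, conc_EFG = efg),
                               tg)
    max(traj$C)
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("observable projection encodes the reporter physics", {
  net <- build_network(row1())
  traj <- integrate_ensemble(net, reaction_conditions(0.1, 0.5), fast_grid())

  # Pi identity: PBP pool is exactly the accommodated pool C + PRE (+ POST)
  pbp_pool <- observable_pool(traj, "PBP")
  expect_equal(pbp_pool, traj$C + traj$PRE)
  # prf and PBP are affinely related
  prf <- project_observable(traj, "prf")
  pbp <- project_observable(traj, "PBP")
  fit <- stats::lm(pbp$fluorescence_au ~ prf$fluorescence_au)
  expect_lt(max(abs(stats::residuals(fit))), 1e-12)

  # L11 channel is biphasic: interior minimum then recovery
  l11 <- project_observable(traj, "L11_Cy3")
  i_min <- which.min(l11$fluorescence_au)
  expect_gt(i_min, 1)
  expect_lt(i_min, nrow(l11))
  expect_gt(utils::tail(l11$fluorescence_au, 1) - min(l11$fluorescence_au),
            0.1 * (l11$fluorescence_au[1] - min(l11$fluorescence_au)))

  # accommodation reporters are monotone
  expect_true(all(diff(prf$fluorescence_au) <= 1e-12))
  expect_true(all(diff(pbp$fluorescence_au) >= -1e-12))

  expect_error(project_observable(traj, "nope"))
})

test_that("uniform rate rescaling emulates the temperature change", {
  r <- scale_rates(row2(), 0.5)
  expect_equal(r$k3, 19.9 / 2)
  expect_equal(kd_complex_b(r), kd_complex_b(row2()))  # Kd is scale-free
  # temperature_scale = 0.5 must equal integrating the halved rates
  tg <- fast_grid()
  t1 <- integrate_ensemble(build_network(row2()),
                           reaction_conditions(0.1, 0.5, temperature_scale = 0.5),
                           tg)
  t2 <- integrate_ensemble(build_network(r), reaction_conditions(0.1, 0.5), tg)
  expect_equal(t1$C, t2$C, tolerance = 1e-9)
})
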