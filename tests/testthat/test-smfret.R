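test_that("single-state limit: occupancy times are Exp(k4)", {
  # k3 very fast, single exit branch: bound dwell ~ Exp(k4)
  rates <- rate_constants(50, 0, 1e5, 6.5)
  cond <- reaction_conditions(0, 0.01)
  durs <- unlist(lapply(1:300, function(i) {
    bound_intervals(simulate_molecule(rates, cond, 120, seed = 1000 + i))$duration
  }))
  expect_gt(length(durs), 1e3)
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 1 / 6.5), 3 * se)
})

test_that("two-stage chain: mean bound time matches 1/k3' + 1/(k4'+k4A')", {
  rates <- rate_constants(100, 120, 19.9, 19.6, k4A = 19.6)
  cond <- reaction_conditions(0, 0.01, temperature_scale = 0.5)
  r <- scale_rates(rates, 0.5)
  expected <- 1 / r$k3 + 1 / (r$k4 + r$k4A)
  durs <- unlist(lapply(1:400, function(i) {
    bound_intervals(simulate_molecule(rates, cond, 120, seed = 2000 + i))$duration
  }))
  expect_gt(length(durs), 1e4)
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - expected), 3 * se)
})

test_that("ensemble-averaged stochastic occupancies match the deterministic
           trajectory", {
  # pseudo-first-order, uncommitted B (full reverse branch) so the
  # stochastic model is the exact counterpart of the ODE network
  rates <- rate_constants(50, 30, 10, 9.8, k4A = 9.8)
  cond <- reaction_conditions(0, 0.01)
  n_mol <- 4000
  checkpoints <- seq(0.1, 3, length.out = 10)
  set.seed(421)
  seeds <- sample.int(.Machine$integer.max - 1L, n_mol)
  states <- vapply(seq_len(n_mol), function(i) {
    p <- simulate_molecule(rates, cond, 3.1, seed = seeds[i],
                           committed = FALSE, recycle = FALSE)
    state_at(p, checkpoints)
  }, character(length(checkpoints)))

  net <- build_network(rate_constants(50, 30, 10, 9.8, k4A = 9.8,
                                      k_m4A = 0), mode = "full")
  traj <- integrate_ensemble(net, reaction_conditions(1e-5, 0.01),
                             c(0, checkpoints))
  for (sp in c("B", "C", "PRE")) {
    p_obs <- rowMeans(states == sp)
    p_ode <- (traj[[sp]] / 1e-5)[-1]
    se <- sqrt(pmax(p_ode * (1 - p_ode), 1e-12) / n_mol)
    expect_true(all(abs(p_obs - p_ode) <= 3 * se + 1e-4),
                label = paste("occupancy of", sp))
  }
})

test_that("rendering obeys the ratio and frame-integration identities", {
  # fully bound frames report exactly E
  p <- structure(tibble::tibble(time = c(0, 0.011 * 10, 0.011 * 20),
                                state = c("empty", "B", "PRE")),
                 class = c("sm_path", class(tibble::tibble())),
                 duration = 0.011 * 40)
  attr(p, "conditions") <- reaction_conditions(0, 0.01)
  tr <- render_trace(p, efficiency = 0.69, total_intensity = 1000,
                     noise_sigma = 0, pre_injection = 0)
  expect_equal(tr$fret[11:20], rep(0.69, 10))
  # jumps at exact frame boundaries: no fractional frames
  expect_equal(sum(tr$I_cy5 > 0), 10)
  expect_equal(tr$I_cy5[11:20], rep(690, 10))
  expect_equal(tr$fret[c(1:10, 21:40)], rep(0, 30))

  # a mid-frame jump yields the arithmetic mean of the two levels
  p2 <- structure(tibble::tibble(time = c(0, 0.011 * 10, 0.011 * 20.5),
                                 state = c("empty", "B", "PRE")),
                  class = c("sm_path", class(tibble::tibble())),
                  duration = 0.011 * 40)
  attr(p2, "conditions") <- reaction_conditions(0, 0.01)
  tr2 <- render_trace(p2, efficiency = 0.69, total_intensity = 1000,
                      noise_sigma = 0, pre_injection = 0)
  expect_equal(tr2$I_cy5[21], 690 / 2)
  expect_equal(tr2$I_cy3[21], 310 / 2)
  # the ratio is scale-invariant, so the half-occupied frame still reads E
  expect_equal(tr2$fret[21], 0.69)

  expect_error(render_trace(p, efficiency = 1.2, noise_sigma = 0), "between")
  expect_error(render_trace(p, efficiency = 0.5, noise_sigma = -1), ">= 0")
})

test_that("event detection is exact on noiseless step traces", {
  tr <- step_trace(300, 100, 120)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 120)
  expect_equal(ev$duration, 20 * 0.011)
  expect_equal(ev$mean_fret, 0.9)

  # events at the minimum length are kept, shorter ones dropped
  tr2 <- step_trace(100, 50, 52)
  expect_equal(nrow(detect_events(tr2)), 1)
  tr3 <- step_trace(100, 50, 51)
  expect_equal(nrow(detect_events(tr3, reference = 1000)), 0)

  # all-background traces yield an empty event table, not an error
  zero <- make_sm_trace(numeric(200), numeric(200), total_intensity = 1000)
  expect_equal(nrow(detect_events(zero)), 0)
  set.seed(9)
  noise_only <- make_sm_trace(stats::rnorm(500, 0, 50),
                              stats::rnorm(500, 0, 50),
                              total_intensity = 1000)
  expect_equal(nrow(detect_events(noise_only)), 0)
})

test_that("detected boundaries stay within one frame of truth at 5% noise", {
  set.seed(77)
  n_tr <- 200
  hits <- 0L; total <- 0L
  for (i in seq_len(n_tr)) {
    start <- sample(30:150, 1)
    len <- sample(5:60, 1)
    w <- numeric(250); w[(start + 1):(start + len)] <- 1
    I3 <- 0.1 * 1000 * w + stats::rnorm(250, 0, 50)
    I5 <- 0.9 * 1000 * w + stats::rnorm(250, 0, 50)
    ev <- detect_events(make_sm_trace(I3, I5, total_intensity = 1000))
    total <- total + 2L
    if (nrow(ev) == 1) {
      hits <- hits + (abs(ev$start_frame - start) <= 1) +
        (abs(ev$end_frame - (start + len)) <= 1)
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("dwell fitting is consistent for exponential samples and flags
           degenerate input", {
  set.seed(123)
  d <- stats::rexp(1e4, 1 / 0.155)
  f <- fit_dwell_distribution(d)
  se <- 0.155 / sqrt(1e4)
  expect_lt(abs(f$t_dissoc - 0.155), 3 * se)
  expect_equal(f$k_dissoc, 1 / f$t_dissoc)

  expect_warning(fd <- fit_dwell_distribution(rep(0.5, 100)), "degenerate")
  expect_true(fd$degenerate)
  expect_error(fit_dwell_distribution(numeric(0)), "no events")
  expect_warning(fit_dwell_distribution(stats::rexp(10, 5)), "imprecise")
})

test_that("dwell time from the full pipeline matches the analytic occupancy
           of the branched exit", {
  cfg <- smfret_config(seed = 88, n_molecules = 150)
  ds <- gen_smfret_dataset(cfg, collect = "events")
  r <- scale_rates(cfg$rates, cfg$temperature_scale)
  expected <- 1 / r$k3 + 1 / (r$k4 + r$k4A)
  f <- suppressWarnings(fit_dwell_distribution(pooled_events(ds)))
  expect_equal(f$t_dissoc, expected, tolerance = 0.10)
})

test_that("dwell times are invariant to EF-G capture of the PRE complex", {
  base <- smfret_config(seed = 91, n_molecules = 80)
  with_efg <- smfret_config(
    seed = 91, n_molecules = 80,
    rates = rate_constants(100, 120, 19.9, 19.6, k4A = 19.6, k_efg = 2),
    conc_EFG = 4)
  d0 <- suppressWarnings(fit_dwell_distribution(
    pooled_events(gen_smfret_dataset(base, collect = "events"))))
  d1 <- suppressWarnings(fit_dwell_distribution(
    pooled_events(gen_smfret_dataset(with_efg, collect = "events"))))
  expect_equal(d1$t_dissoc, d0$t_dissoc, tolerance = 0.05)
})
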