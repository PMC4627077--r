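test_that("ensemble generation is deterministic and reduces to the forward
           model without noise", {
  cfg <- ensemble_config(seed = 3, conc_TC = c(0.4, 1.0), noise_sigma = 0,
                         time_grid = fast_grid(1))
  ds1 <- gen_ensemble_dataset(cfg)
  ds2 <- gen_ensemble_dataset(cfg)
  expect_identical(ds1$data, ds2$data)

  # noiseless traces equal project_observable output exactly
  net <- build_network(cfg$rates)
  traj <- integrate_ensemble(net, reaction_conditions(0.1, 0.4), fast_grid(1))
  ref <- project_observable(traj, "L11_Cy3")
  got <- ds1$data[[which(ds1$channel == "L11_Cy3" & ds1$conc_TC == 0.4)]]
  expect_identical(got$fluorescence_au, ref$fluorescence_au)

  # with noise: deterministic under the seed, different under another
  cfgn <- ensemble_config(seed = 3, conc_TC = 0.4, noise_sigma = 0.01,
                          time_grid = fast_grid(1))
  expect_identical(gen_ensemble_dataset(cfgn)$data,
                   gen_ensemble_dataset(cfgn)$data)
  cfgn2 <- ensemble_config(seed = 4, conc_TC = 0.4, noise_sigma = 0.01,
                           time_grid = fast_grid(1))
  expect_false(identical(gen_ensemble_dataset(cfgn)$data[[1]],
                         gen_ensemble_dataset(cfgn2)$data[[1]]))

  expect_error(ensemble_config(seed = 1, channels = "L12_Cy3"), "unknown")
  expect_error(ensemble_config(channels = "prf"), "mandatory")
})

test_that("manifests echo the config and carry complete ground truth", {
  cfg <- ensemble_config(seed = 12, conc_TC = 0.4, noise_sigma = 0,
                         time_grid = fast_grid(1))
  m <- attr(gen_ensemble_dataset(cfg), "manifest")
  expect_identical(m$seed, 12L)
  expect_identical(m$rates$k12, 36)

  sm <- smfret_config(seed = 12, n_molecules = 5)
  ds <- gen_smfret_dataset(sm, collect = "events")
  expect_identical(ds$manifest$seed, 12L)
  expect_true(all(c("molecule", "start", "end", "duration") %in%
                    names(ds$truth)))
  expect_gt(nrow(ds$truth), 0)
})

test_that("single noiseless molecule: detection reproduces the manifest
           interval exactly", {
  cfg <- smfret_config(seed = 31, n_molecules = 1, noise_sigma = 0)
  ds <- gen_smfret_dataset(cfg, collect = "all")
  truth <- ds$truth
  ev <- detect_events(ds$traces[[1]], reference = cfg$total_intensity)
  dt <- cfg$frame_interval
  inj <- attr(ds$traces[[1]], "injection_frame")
  # every detected event corresponds to a truth interval with both
  # boundaries within one camera frame
  for (i in seq_len(nrow(ev))) {
    ds_start <- abs(truth$start / dt + inj - ev$start_frame[i])
    ds_end <- abs(truth$end / dt + inj - ev$end_frame[i])
    expect_lte(min(pmax(ds_start, ds_end)), 1)
  }
  # every truth interval comfortably above the 2-frame floor is detected
  solid <- truth[truth$duration >= 3 * dt, ]
  for (i in seq_len(nrow(solid))) {
    covered <- any(ev$start_frame <= solid$start[i] / dt + inj + 1 &
                     ev$end_frame >= solid$end[i] / dt + inj - 1)
    expect_true(covered)
  }

  expect_identical(gen_smfret_dataset(cfg, collect = "events")$truth, truth)
  expect_error(smfret_config(seed = 1, n_molecules = 0), "> 0")
})

test_that("rate-vs-concentration generator: exact MM route and ordered
           forward route", {
  pts <- gen_rate_vs_concentration(route = "mm", Vmax = 11.0, KM = 0.56,
                                   concentrations = c(0, 0.2, 0.4, 0.6, 0.9, 1.2))
  expect_equal(pts$rate, 11.0 * pts$concentration / (0.56 + pts$concentration))
  expect_equal(pts$rate[pts$concentration == 0], 0)

  fw <- gen_rate_vs_concentration(route = "forward",
                                  concentrations = c(0.2, 0.6, 1.2),
                                  time_grid = fast_grid(2))
  w <- tidyr::pivot_wider(fw, names_from = channel, values_from = rate)
  expect_true(all(w$prf > w$tRNA_Cy3))
})

test_that("apparent EF-Tu:tRNA separation rate converges toward the
           accommodation rate with increasing EF-G capture", {
  gaps <- vapply(c(0, 1, 2, 4, 20), function(efg) {
    w <- tidyr::pivot_wider(
      gen_rate_vs_concentration(route = "forward", concentrations = 0.4,
                                conc_EFG = efg, time_grid = fast_grid(2)),
      names_from = channel, values_from = rate)
    c(acc = w$prf, gap = w$prf - w$tRNA_Cy3)
  }, numeric(2))
  # k'_tRNA rises monotonically toward k'_acc ...
  expect_true(all(diff(gaps["gap", ]) < 0))
  expect_true(all(gaps["gap", ] > 0))
  # ... while k'_acc itself is unchanged within 2%
  expect_lt(max(abs(gaps["acc", ] / gaps["acc", 1] - 1)), 0.02)
})
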