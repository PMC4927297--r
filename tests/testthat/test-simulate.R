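test_that("noise-free rat train trace carries the stated jump and recovery", {
  fx <- noisefree_pipeline("rat_control")
  # full 1.52 pF jump on the 18.87 pF baseline at the last pulse offset
  expect_equal(ts_interp(fx$cm, 0) - fx$scn$baseline_cm_pF, 1.52,
               tolerance = 1e-9)
  # normalised recovery matches the closed form on the whole limb
  tt <- seq(0, 60, by = 2.5)
  expect_equal(ts_interp(fx$cmn, tt), rat_recovery_closed_form(tt),
               tolerance = 1e-8)
})

test_that("no-endocytosis limit gives a flat post-stimulus trace", {
  scn <- scenario_preset("rat_control", noise_sd = 0,
                         endo = endocytosis_params(0, data.frame(fraction = 1,
                                                                 tau_s = 1e9)))
  cm <- simulate_capacitance(scn)
  post <- ts_window(cm, 0, Inf)
  expect_lt(diff(range(post$v)), 1e-6)
})

test_that("blocked re-acidification and full stranding pin the quench at 1", {
  fx <- noisefree_pipeline("bafilomycin")
  expect_true(all(abs(fx$rep$q_ideal$v - 1) < 1e-12))
  scn <- scenario_preset("rat_control", noise_sd = 0, stranding_frac = 1)
  expect_true(all(abs(simulate_reporter(scn)$q_ideal$v - 1) < 1e-12))
})

test_that("reporter bookkeeping conserves the exocytosed pool", {
  for (preset in c("rat_control", "bulk_2s", "cam_peptide", "four_pulse")) {
    st <- noisefree_pipeline(preset)$rep$state
    expect_lt(max(abs(st$surface + st$endocytosed_unacid + st$acidified -
                        st$exocytosed)), 1e-9)
    # and the pool is complete (= 1) from the stimulus end on
    expect_true(all(abs(st$exocytosed[st$t >= 0] - 1) < 1e-12))
  }
})

test_that("quench trace is non-increasing once exocytosis has ceased", {
  for (preset in c("rat_control", "mouse_wt", "bulk_2s")) {
    q <- noisefree_pipeline(preset)$rep$q_ideal
    expect_true(all(diff(q$v) <= 1e-12))
  }
})

test_that("infinite delay reproduces the re-acidification-blocked trace", {
  blocked <- scenario_preset("rat_control", noise_sd = 0,
                             reacid_blocked = TRUE)
  inf_delay <- scenario_preset("rat_control", noise_sd = 0,
                               reacid = reacidification_params(Inf, 38.7))
  expect_identical(simulate_reporter(blocked)$q_ideal$v,
                   simulate_reporter(inf_delay)$q_ideal$v)
})

test_that("identical seeds reproduce bit-identical traces", {
  a <- simulate_capacitance(scenario_preset("rat_control", seed = 42))
  b <- simulate_capacitance(scenario_preset("rat_control", seed = 42))
  expect_identical(a$v, b$v)
  fa <- simulate_reporter(scenario_preset("rat_control", seed = 42))$fluor
  fb <- simulate_reporter(scenario_preset("rat_control", seed = 42))$fluor
  expect_identical(fa$v, fb$v)
  c2 <- simulate_capacitance(scenario_preset("rat_control", seed = 43))
  expect_false(identical(a$v, c2$v))
})

test_that("convolution forward model matches the event-based oracle", {
  for (preset in c("rat_control", "mouse_wt")) {
    fx <- noisefree_pipeline(preset)
    mc <- mc_reporter_oracle(fx$scn, n = 2e4)
    qv <- ts_interp(fx$rep$q_ideal, mc$t)
    expect_true(all(abs(qv - mc$q) <= 3 * mc$se + 1e-9))
  }
})

test_that("neighbour ROI encodes the bleach model it was given", {
  flat <- scenario_preset("rat_control", noise_sd = 0)
  nb <- simulate_neighbor_roi(flat)
  expect_lt(diff(range(nb$v)), 1e-12)

  lin <- scenario_preset("rat_control", noise_sd = 0,
                         bleach = list(model = "linear", rate = 4e-4))
  nbl <- simulate_neighbor_roi(lin)
  slope <- stats::coef(stats::lm(nbl$v ~ nbl$t))[2]
  expect_equal(unname(slope), -4e-4, tolerance = 1e-9)

  ex <- scenario_preset("rat_control", noise_sd = 0,
                        bleach = list(model = "exponential", rate = 6e-4))
  nbe <- simulate_neighbor_roi(ex)
  lfit <- stats::lm(log(nbe$v) ~ nbe$t)
  expect_equal(unname(stats::coef(lfit)[2]), -6e-4, tolerance = 1e-9)
  expect_lt(summary(lfit)$sigma, 1e-10)    # log-trace exactly linear
})

test_that("reporter simulation rejects a foreign capacitance trace", {
  scn <- scenario_preset("rat_control", noise_sd = 0)
  other <- simulate_capacitance(scenario_preset("mouse_wt", noise_sd = 0))
  expect_error(simulate_reporter(scn, other), "provenance")
})

test_that("acid puffs de-quench exactly the surface-exposed reporter", {
  fx <- noisefree_pipeline("rat_control")
  # pre-stimulus puff at lumen pH reads out the stranded surface density
  pp <- puff_events(-20)
  f <- simulate_acid_puff(fx$scn, fx$rep$state, pp, fx$rep$fluor)
  expect_equal(f$meta$puff_dF, 0.48, tolerance = 1e-9)
  # no surface reporter -> zero transient
  scn0 <- scenario_preset("rat_control", noise_sd = 0,
                          surface_stranded_density = 0)
  rep0 <- simulate_reporter(scn0)
  st0 <- rep0$state
  st0$surface <- 0 * st0$surface
  f0 <- simulate_acid_puff(scn0, st0, pp, rep0$fluor)
  expect_equal(f0$meta$puff_dF, 0, tolerance = 1e-12)
  # puff outside the span is an error
  expect_error(simulate_acid_puff(fx$scn, fx$rep$state, puff_events(500),
                                  fx$rep$fluor),
               "outside")
})
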