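test_that("Henderson-Hasselbalch mapping behaves as a titration curve", {
  p <- reacidification_params(14, 38.7)
  expect_equal(hh_fluorescence(7.05, p), 0.5)
  # frozen closed-form values at the two operating pH points
  expect_equal(hh_fluorescence(5.5, p), 1 / (1 + 10^(5.5 - 7.05)))
  expect_equal(round(hh_fluorescence(5.5, p), 4), 0.9726)
  expect_equal(round(hh_fluorescence(7.4, p), 4), 0.3088)
  pHs <- seq(4, 10, by = 0.25)
  expect_true(all(diff(hh_fluorescence(pHs, p)) < 0))
  expect_gt(hh_fluorescence(5.5, p), hh_fluorescence(7.4, p))
})

test_that("recovery kernel is a delayed, bounded, monotone de-quench", {
  p <- reacidification_params(14, 38.7)
  s <- seq(0, 400, by = 0.5)
  g <- recovery_kernel(s, p)
  expect_true(all(g[s < 14] == 0))
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(recovery_kernel(4000, p), 1, tolerance = 1e-9)
  # closed form at one kernel time constant past the delay
  pH1 <- 5.5 + 1.9 * exp(-1)
  phi <- function(x) 1 / (1 + 10^(x - 7.05))
  g1 <- (phi(pH1) - phi(7.4)) / (phi(5.5) - phi(7.4))
  expect_equal(recovery_kernel(14 + 38.7, p), g1, tolerance = 1e-12)
  expect_equal(round(g1, 3), 0.855)
})

test_that("forward model limits: infinite delay and instant re-acidification", {
  fx <- noisefree_pipeline("rat_control")
  q_inf <- predict_quench(fx$cmn, reacidification_params(Inf, 38.7))
  expect_true(all(q_inf$v == 1))
  q_fast <- predict_quench(fx$cmn, reacidification_params(0, 1e-4))
  expect_equal(q_fast$v, ts_interp(fx$cmn, q_fast$t), tolerance = 0.01)
})

test_that("per-organelle and global-delay modes agree for instantaneous endocytosis", {
  # all retrieval in one sharp drop well after the stimulus
  tt <- seq(0, 120, by = 0.25)
  v <- ifelse(tt < 10, 1, 0.1)
  cmn <- timeseries(tt, v, "norm")
  p <- reacidification_params(14, 30)
  q1 <- predict_quench(cmn, p, mode = "per_organelle")
  q2 <- predict_quench(cmn, p, mode = "global_delay")
  # delay shifted about the single retrieval instant: curves coincide up to
  # the one-sample smearing of the step
  expect_lt(max(abs(ts_interp(q1, seq(0, 9, 1)) -
                      ts_interp(q2, seq(0, 9, 1)))), 1e-9)
  expect_lt(max(abs(ts_interp(q1, seq(30, 120, 1)) -
                      ts_interp(q2, seq(30, 120, 1)))), 0.02)
})

test_that("non-monotone recovery limbs are flagged in the prediction meta", {
  tt <- seq(0, 60, by = 0.25)
  v <- 0.2 + 0.8 * exp(-tt / 20) + 0.1 * sin(tt / 3)
  q <- predict_quench(timeseries(tt, v, "norm"),
                      reacidification_params(5, 20))
  expect_true(q$meta$nonmonotone_warning)
})

test_that("grid fit recovers the generating delay and time constant", {
  fx <- noisefree_pipeline("rat_control")
  rf <- fit_reacidification(fx$cmn, fx$q)
  expect_lt(abs(rf$delay_s - 14), 0.5)
  expect_lt(abs(rf$tau_acid_s - 38.7) / 38.7, 0.02)
  expect_false(rf$boundary)
  expect_false(rf$unidentifiable)
  # sse surface argmin sits at the generating parameters at grid resolution
  srf <- rf$grid_surface
  best <- srf[which.min(srf$sse), ]
  expect_lte(abs(best$delay_s - 14), 1)
  expect_lt(abs(best$tau_s - 38.7) / 38.7, 0.10)

  fm <- noisefree_pipeline("mouse_wt")
  rfm <- fit_reacidification(fm$cmn, fm$q)
  expect_lt(abs(rfm$delay_s - 12), 0.5)
  expect_lt(abs(rfm$tau_acid_s - 18.9) / 18.9, 0.02)
})

test_that("a flat quench trace is flagged unidentifiable", {
  fx <- noisefree_pipeline("bafilomycin")
  rf <- fit_reacidification(fx$cmn, fx$q,
                            delay_grid = seq(0, 40, by = 5),
                            tau_grid = c(10, 40, 160))
  expect_true(rf$unidentifiable)
  expect_true(rf$boundary)
})

test_that("global-delay fitting mode runs and reports its mode", {
  fx <- noisefree_pipeline("rat_control")
  rf <- fit_reacidification(fx$cmn, fx$q, mode = "global_delay",
                            delay_grid = seq(0, 30, by = 5),
                            tau_grid = exp(seq(log(10), log(100),
                                               length.out = 8)))
  expect_identical(rf$mode, "global_delay")
  expect_true(is.finite(rf$sse))
})

test_that("delayed-exponential fit is exact on its own family", {
  tt <- seq(0, 190, by = 4)
  qv <- 0.13 + (1 - 0.13) * pmin(1, exp(-(tt - 16) / 59.7))
  fd <- fit_delayed_exponential(timeseries(tt, qv, "q_norm"))
  expect_equal(fd$delay_s, 16, tolerance = 1e-9)
  expect_equal(fd$tau_s, 59.7, tolerance = 1e-4)
  expect_equal(fd$asymptote, 0.13, tolerance = 1e-6)
  expect_false(fd$tau_at_bound)

  # fixed-asymptote variant
  fdf <- fit_delayed_exponential(timeseries(tt, qv, "q_norm"),
                                 asymptote = "fixed", A_fixed = 0.13)
  expect_equal(fdf$tau_s, 59.7, tolerance = 1e-4)
})

test_that("long rat recording yields the printed apparent delayed exponential", {
  fx <- noisefree_pipeline("rat_control", t_post_s = 190, imaging_hz = 0.25)
  fd <- fit_delayed_exponential(fx$q)
  # qualitative check against the printed 16 s delay, tau 55.5-59.7 s
  expect_gt(fd$delay_s, 8); expect_lt(fd$delay_s, 24)
  expect_gt(fd$tau_s, 40); expect_lt(fd$tau_s, 80)
})

test_that("a non-recovering trace drives the time constant to its bound", {
  tt <- seq(0, 60, by = 2)
  fd <- fit_delayed_exponential(timeseries(tt, rep(1, length(tt)), "q_norm"),
                                tau_range = c(1, 500))
  expect_true(fd$tau_at_bound)
})
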