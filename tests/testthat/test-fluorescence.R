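test_that("bleach correction removes the bleach the generator applied", {
  # constant neighbour: target passes through unchanged
  fx <- noisefree_pipeline("rat_control")
  nb_flat <- simulate_neighbor_roi(fx$scn)
  out <- bleach_correct(fx$rep$fluor, nb_flat, "linear")
  expect_equal(out$v, fx$rep$fluor$v, tolerance = 1e-9)

  clean <- fx$rep$fluor
  for (mdl in c("linear", "exponential")) {
    scn <- scenario_preset("rat_control", noise_sd = 0,
                           bleach = list(model = mdl, rate = 5e-4))
    f <- simulate_reporter(scn)$fluor
    nb <- simulate_neighbor_roi(scn)
    corr <- bleach_correct(f, nb, model = "auto")
    expect_identical(corr$meta$bleach_correction$model, mdl)
    # corrected trace matches the bleach-free ground truth within the
    # scenario's nominal noise amplitude (0.03 of the stimulus dF)
    expect_lt(max(abs(corr$v - clean$v)), 0.03 * scn$dF_stim)
  }
})

test_that("bleach correction is idempotent once both ROIs are corrected", {
  scn <- scenario_preset("rat_control", noise_sd = 0,
                         bleach = list(model = "exponential", rate = 5e-4))
  f <- simulate_reporter(scn)$fluor
  nb <- simulate_neighbor_roi(scn)
  corr <- bleach_correct(f, nb, "auto")
  nb_corr <- bleach_correct(nb, nb, "auto")
  corr2 <- bleach_correct(corr, nb_corr, "auto")
  expect_lt(max(abs(corr2$v - corr$v)), 1e-6)
})

test_that("a neighbour shorter than the target is rejected", {
  fx <- noisefree_pipeline("rat_control")
  nb <- ts_window(simulate_neighbor_roi(fx$scn), -10, 30)
  expect_error(bleach_correct(fx$rep$fluor, nb), "shorter")
})

test_that("normalise-and-invert round-trips the generator quench trace", {
  for (preset in c("rat_control", "mouse_wt", "bulk_2s", "cam_peptide")) {
    fx <- noisefree_pipeline(preset)
    q <- fx$q
    expect_equal(q$trace$v[q$trace$t >= 0],
                 ts_interp(fx$rep$q_ideal, q$trace$t[q$trace$t >= 0]),
                 tolerance = 1e-9)
    # stimulus-end sample is 1 by construction
    expect_equal(ts_interp(q$trace, 0), 1, tolerance = 1e-9)
  }
})

test_that("the two normalisation modes are affinely equivalent", {
  fx <- noisefree_pipeline("rat_control")
  q1 <- normalize_invert(fx$rep$fluor, mode = "delta_f")
  q2 <- normalize_invert(fx$rep$fluor, mode = "initial")
  expect_equal(endpoint_metric(q1, 60), endpoint_metric(q2, 60),
               tolerance = 1e-12)
})

test_that("a trace without stimulus response cannot be normalised", {
  flat <- timeseries(seq(-30, 60, by = 2), rep(1, 46), "au")
  expect_error(normalize_invert(flat), "non-positive stimulus dF")
})

test_that("quench endpoints agree with the printed group means", {
  expect_lt(abs(endpoint_metric(noisefree_pipeline("rat_control")$q, 60) -
                  0.47), 0.10)
  baf <- noisefree_pipeline("bafilomycin")$q
  expect_true(all(abs(baf$trace$v[baf$trace$t >= 0] - 1) < 1e-9))
  expect_lt(abs(endpoint_metric(noisefree_pipeline("bulk_2s")$q, 40) -
                  0.93), 0.07)
})

test_that("puff metrics read out the surface pool and are scale invariant", {
  pp <- puff_events(c(-20, 40))

  # identical surface pool pre/post: flat trace, two equal transients
  tt <- seq(-30, 60, by = 2)
  v <- rep(1, length(tt))
  v[tt >= -20 & tt < -15] <- 1.3
  v[tt >= 40 & tt < 45] <- 1.3
  pm_flat <- puff_dequench(timeseries(tt, v, "au"), pp)
  expect_equal(pm_flat$ratio, 1, tolerance = 1e-12)

  ratio_for <- function(preset) {
    fx <- noisefree_pipeline(preset)
    f <- simulate_acid_puff(fx$scn, fx$rep$state, pp, fx$rep$fluor)
    puff_dequench(f, pp)
  }
  ctrl <- ratio_for("rat_control")
  cam <- ratio_for("cam_peptide")
  bulk <- ratio_for("bulk_2s")
  # stranding raises the post/pre ratio above control
  expect_gt(cam$ratio, ctrl$ratio)
  # bulk endocytosis internalises the reporter: post pool equals the
  # state-log surface fraction plus the stranded density
  fx <- noisefree_pipeline("bulk_2s")
  surf40 <- stats::approx(fx$rep$state$t, fx$rep$state$surface, 40)$y
  expected_post <- (fx$scn$surface_stranded_density + surf40) * fx$scn$dF_stim
  expect_equal(bulk$post_dF, expected_post, tolerance = 0.1)
  expect_lt(abs(bulk$ratio - 1), 0.25)

  # global fluorescence scaling leaves the ratio unchanged
  f <- simulate_acid_puff(fx$scn, fx$rep$state, pp, fx$rep$fluor)
  f_scaled <- timeseries(f$t, f$v * 12.5, f$units, f$meta)
  expect_equal(puff_dequench(f_scaled, pp)$ratio,
               puff_dequench(f, pp)$ratio, tolerance = 1e-12)

  expect_error(puff_dequench(f, puff_events(-20)), "at least")
})

test_that("surface density arithmetic reproduces the per-area numbers", {
  d <- surface_density(0.48, 18.87, 1.0, 1.52)
  expect_equal(d$surface_density, 0.48 / 18.87, tolerance = 1e-12)
  expect_equal(d$vesicular_density, 1 / 1.52, tolerance = 1e-12)
  expect_equal(d$ratio, (1 / 1.52) / (0.48 / 18.87), tolerance = 1e-12)

  expect_equal(surface_density(0.2, 10, 0.4, 20)$ratio, 1)
  expect_equal(surface_density(0.96, 18.87, 2, 1.52)$ratio,
               surface_density(0.48, 18.87, 1, 1.52)$ratio)
  expect_error(surface_density(0, 1, 1, 1), "> 0")
})
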