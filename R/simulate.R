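# normalized recovery factor of an increment u seconds after its own
# endocytosis clock started: plateau + (1 - plateau) * sum a_j exp(-u/tau_j)
cm_recovery_frac <- function(u, endo) {
  out <- rep(1, length(u))
  pos <- which(u >= 0)
  if (length(pos)) {
    dec <- numeric(length(pos))
    for (j in seq_len(nrow(endo$components))) {
      dec <- dec + endo$components$fraction[j] *
        exp(-u[pos] / endo$components$tau_s[j])
    }
    out[pos] <- endo$plateau_frac + (1 - endo$plateau_frac) * dec
  }
  out
}

# noise-free capacitance in pF at arbitrary times
cm_ideal <- function(scn, t) {
  offs <- pulse_offsets(scn$protocol)
  v <- rep(scn$baseline_cm_pF, length(t))
  for (i in seq_along(offs)) {
    Ji <- scn$jump_total_pF * scn$per_pulse_weights[i]
    clock <- if (scn$endo_start == "train_end") t else t - offs[i]
    v <- v + Ji * (t >= offs[i] - 1e-12) * cm_recovery_frac(clock, scn$endo)
  }
  v
}

# normalized endocytic flux e(t): -d/dt of the normalized capacitance,
# integrating to (1 - plateau) over the full recovery
endo_flux <- function(scn, t) {
  offs <- pulse_offsets(scn$protocol)
  comp <- scn$endo$components
  p <- scn$endo$plateau_frac
  e <- numeric(length(t))
  if (scn$endo_start == "train_end") {
    pos <- t >= 0
    for (j in seq_len(nrow(comp))) {
      e[pos] <- e[pos] + (1 - p) * comp$fraction[j] / comp$tau_s[j] *
        exp(-t[pos] / comp$tau_s[j])
    }
  } else {
    for (i in seq_along(offs)) {
      pos <- t >= offs[i]
      u <- t[pos] - offs[i]
      for (j in seq_len(nrow(comp))) {
        e[pos] <- e[pos] + scn$per_pulse_weights[i] * (1 - p) *
          comp$fraction[j] / comp$tau_s[j] * exp(-u / comp$tau_s[j])
      }
    }
  }
  e
}

# cumulative retrieved fraction F(t) = integral of endo_flux
endo_cum <- function(scn, t) {
  offs <- pulse_offsets(scn$protocol)
  comp <- scn$endo$components
  p <- scn$endo$plateau_frac
  FF <- numeric(length(t))
  if (scn$endo_start == "train_end") {
    pos <- t >= 0
    dec <- numeric(sum(pos))
    for (j in seq_len(nrow(comp))) {
      dec <- dec + comp$fraction[j] * exp(-t[pos] / comp$tau_s[j])
    }
    FF[pos] <- (1 - p) * (1 - dec)
  } else {
    for (i in seq_along(offs)) {
      pos <- t >= offs[i]
      u <- t[pos] - offs[i]
      dec <- numeric(sum(pos))
      for (j in seq_len(nrow(comp))) {
        dec <- dec + comp$fraction[j] * exp(-u / comp$tau_s[j])
      }
      FF[pos] <- FF[pos] + scn$per_pulse_weights[i] * (1 - p) * (1 - dec)
    }
  }
  FF
}

# cumulative exocytosed fraction X(t): steps at pulse offsets
exo_cum <- function(scn, t) {
  offs <- pulse_offsets(scn$protocol)
  X <- numeric(length(t))
  for (i in seq_along(offs)) {
    X <- X + scn$per_pulse_weights[i] * (t >= offs[i] - 1e-12)
  }
  X
}

bleach_factor <- function(scn, t, t0) {
  switch(scn$bleach$model,
    none = rep(1, length(t)),
    linear = pmax(0, 1 - scn$bleach$rate * (t - t0)),
    exponential = exp(-scn$bleach$rate * (t - t0)))
}

imaging_times <- function(scn) {
  dt <- 1 / scn$imaging_hz
  sort(unique(c(rev(seq(0, -scn$t_pre_s, by = -dt)),
                seq(0, scn$t_post_s, by = dt))))
}

#' Simulate a membrane capacitance trace
#'
#' Baseline capacitance plus per-pulse exocytotic step increments; the
#' recoverable part of each increment then decays as the scenario's mixture
#' of exponentials towards the non-retrieved plateau, with additive Gaussian
#' noise at the capacitance sampling rate. With the default
#' `endo_start = "train_end"` all increments of a compact train start
#' recovering at the last pulse offset (t = 0), so the normalised recovery
#' limb is exactly `plateau + (1 - plateau) sum a_j exp(-t/tau_j)`.
#'
#' @param scn a [scenario_params()] object.
#' @return a [timeseries()] in pF spanning `[-t_pre_s, t_post_s]`.
#' @examples
#' scn <- scenario_preset("rat_control", noise_sd = 0)
#' cm <- simulate_capacitance(scn)
#' ts_interp(cm, 0) - scn$baseline_cm_pF  # the 1.52 pF jump
#' @export
simulate_capacitance <- function(scn) {
  tg <- seq(-scn$t_pre_s, scn$t_post_s, by = 1 / scn$cap_hz)
  v <- cm_ideal(scn, tg)
  if (scn$noise_sd > 0) {
    v <- v + with_seed(scn$seed + 101L,
                       stats::rnorm(length(tg), 0,
                                    scn$noise_sd * scn$jump_total_pF))
  }
  timeseries(tg, v, "pF",
             meta = list(scenario = scn$name, seed = scn$seed,
                         noise_sd = scn$noise_sd,
                         t0 = "last pulse offset"))
}

# reporter bookkeeping on a fine grid; all quantities are fractions of the
# total exocytosed reporter pool (X(t) -> 1 at stimulus end)
reporter_state <- function(scn, dt = 0.01) {
  tg <- seq(-scn$t_pre_s, scn$t_post_s, by = dt)
  X <- exo_cum(scn, tg)
  FF <- endo_cum(scn, tg)
  e <- endo_flux(scn, tg)
  s <- scn$stranding_frac
  if (scn$reacid_blocked || is.infinite(scn$reacid$delay_s)) {
    acid_raw <- numeric(length(tg))
  } else {
    g <- recovery_kernel(seq(0, by = dt, length.out = length(tg)), scn$reacid)
    acid_raw <- conv_flux_kernel(e, g, dt)
    acid_raw <- pmin(pmax(acid_raw, 0), FF)
  }
  acid <- (1 - s) * acid_raw
  endo <- (1 - s) * FF
  surface <- X - endo
  data.frame(t = tg, exocytosed = X, surface = surface,
             endocytosed_unacid = endo - acid, acidified = acid,
             quenched = X - acid)
}

#' Simulate the reporter fluorescence trace and organelle state log
#'
#' Forward-models the pH reporter from the scenario's ground truth: reporter
#' is exposed (quenched) stepwise at each pulse offset, co-retrieved with
#' the membrane according to the endocytic flux, and de-quenched per
#' organelle by the delayed-exponential re-acidification kernel mapped
#' through the Henderson-Hasselbalch curve. The raw trace is emitted at the
#' imaging rate with photobleaching and Gaussian noise applied;
#' `reacid_blocked` scenarios never de-quench, and fully stranded reporter
#' (`stranding_frac = 1`) stays quenched at the surface.
#'
#' @param scn a [scenario_params()] object.
#' @param cm optional capacitance trace from the same scenario; only its
#'   provenance is used (the internal model is noise-free), and a mismatch
#'   between `cm$meta$scenario`/`seed` and `scn` is an error.
#' @return list with `fluor` (raw-unit [timeseries()] at the imaging rate),
#'   `state` (data.frame log: `t`, `exocytosed`, `surface`,
#'   `endocytosed_unacid`, `acidified`, `quenched`, all fractions of the
#'   exocytosed pool), and `q_ideal` (noise-free quench trace for t >= 0,
#'   1 at stimulus end).
#' @export
simulate_reporter <- function(scn, cm = NULL) {
  if (!is.null(cm)) {
    if (!identical(cm$meta$scenario, scn$name) ||
        !identical(cm$meta$seed, scn$seed)) {
      stop("capacitance trace provenance does not match the scenario ",
           "(scenario/seed mismatch)")
    }
  }
  st <- reporter_state(scn)
  t_img <- imaging_times(scn)
  quenched <- stats::approx(st$t, st$quenched, xout = t_img, rule = 2)$y
  bl <- bleach_factor(scn, t_img, t_img[1])
  v <- (1 - scn$dF_stim * quenched) * bl
  if (scn$noise_sd > 0) {
    v <- v + with_seed(scn$seed + 202L,
                       stats::rnorm(length(t_img), 0,
                                    scn$noise_sd * scn$dF_stim))
  }
  fluor <- timeseries(t_img, v, "au",
                      meta = list(scenario = scn$name, seed = scn$seed,
                                  dF_stim = scn$dF_stim, stim_end = 0,
                                  bleach = scn$bleach$model))
  post <- st$t >= -1e-12
  q_ideal <- timeseries(st$t[post], st$quenched[post], "q_norm",
                        meta = list(scenario = scn$name, seed = scn$seed))
  list(fluor = fluor, state = st, q_ideal = q_ideal)
}

#' Superimpose extracellular acid-puff transients on a fluorescence trace
#'
#' During each puff the surface-exposed reporter (pre-existing stranded
#' surface pool plus any exocytosed reporter not yet retrieved) is
#' de-quenched in proportion to
#' `(phi(pH_puff) - phi(pH_surface)) / (phi(pH_lumen) - phi(pH_surface))`,
#' which is 1 when the puff is as acidic as the vesicle lumen.
#'
#' @param scn a [scenario_params()] object.
#' @param state state log from [simulate_reporter()].
#' @param puffs a [puff_events()] data.frame; puffs must fall inside the
#'   trace span and not overlap.
#' @param fluor raw fluorescence trace to decorate; regenerated from `scn`
#'   when `NULL`.
#' @return the fluorescence [timeseries()] with puff transients added;
#'   `meta$puff_dF` records each transient's amplitude in stimulus-dF units.
#' @export
simulate_acid_puff <- function(scn, state, puffs, fluor = NULL) {
  puffs <- puff_events(puffs$onset_s, puffs$duration_s, puffs$pH)  # revalidate
  if (is.null(fluor)) fluor <- simulate_reporter(scn)$fluor
  if (any(puffs$onset_s < fluor$t[1]) ||
      any(puffs$onset_s + puffs$duration_s > fluor$t[length(fluor$t)])) {
    stop("puff events fall outside the trace span")
  }
  phi <- function(pH) hh_fluorescence(pH, scn$reacid)
  den <- phi(scn$reacid$pH_lumen) - phi(scn$reacid$pH_surface)
  v <- fluor$v
  dFs <- numeric(nrow(puffs))
  for (k in seq_len(nrow(puffs))) {
    surf_exo <- stats::approx(state$t, state$surface,
                              xout = puffs$onset_s[k], rule = 2)$y
    pool <- scn$surface_stranded_density + surf_exo
    dF <- pool * (phi(puffs$pH[k]) - phi(scn$reacid$pH_surface)) / den
    dFs[k] <- dF
    inwin <- fluor$t >= puffs$onset_s[k] - 1e-9 &
      fluor$t < puffs$onset_s[k] + puffs$duration_s[k] - 1e-9
    v[inwin] <- v[inwin] + dF * scn$dF_stim
  }
  out <- timeseries(fluor$t, v, fluor$units, fluor$meta)
  out$meta$puff_dF <- dFs
  out$meta$puffs <- puffs
  out
}

#' Simulate an unstimulated neighbour-ROI trace
#'
#' Bleach reference: a constant-fluorescence neighbouring terminal scaled by
#' the scenario's bleach model, with the same additive noise model as the
#' target ROI (independent substream of the scenario seed).
#'
#' @param scn a [scenario_params()] object.
#' @return a raw-unit [timeseries()] at the imaging rate.
#' @export
simulate_neighbor_roi <- function(scn) {
  t_img <- imaging_times(scn)
  v <- bleach_factor(scn, t_img, t_img[1])
  if (scn$noise_sd > 0) {
    v <- v + with_seed(scn$seed + 303L,
                       stats::rnorm(length(t_img), 0,
                                    scn$noise_sd * scn$dF_stim))
  }
  timeseries(t_img, v, "au",
             meta = list(scenario = scn$name, seed = scn$seed,
                         role = "neighbor", bleach = scn$bleach$model))
}

#' Event-based Monte-Carlo oracle for the quench trace
#'
#' Independent check of the convolution forward model: draws discrete
#' organelles with endocytosis times from the scenario's endocytic flux
#' (mixture of exponentials per component, a `plateau_frac` share never
#' retrieved) and lets each follow the recovery kernel individually. Used in
#' tests to bound the convolution prediction within Monte-Carlo error.
#'
#' @param scn a [scenario_params()] object.
#' @param n number of organelles (default 1e5).
#' @param t_eval evaluation times (default: imaging samples at t >= 0).
#' @param seed RNG seed (default: scenario seed substream).
#' @return data.frame `t`, `q` (mean quench), `se` (Monte-Carlo standard
#'   error of `q`).
#' @export
mc_reporter_oracle <- function(scn, n = 1e5, t_eval = NULL, seed = NULL) {
  if (is.null(t_eval)) {
    t_img <- imaging_times(scn)
    t_eval <- t_img[t_img >= 0]
  }
  if (is.null(seed)) seed <- scn$seed + 404L
  comp <- scn$endo$components
  offs <- pulse_offsets(scn$protocol)
  s <- scn$stranding_frac
  T_endo <- with_seed(seed, {
    fate <- stats::runif(n)
    Tv <- rep(Inf, n)
    idx <- fate >= scn$endo$plateau_frac   # retrieved organelles
    nr <- sum(idx)
    j <- sample.int(nrow(comp), nr, replace = TRUE, prob = comp$fraction)
    T0 <- stats::rexp(nr, rate = 1 / comp$tau_s[j])
    if (scn$endo_start == "pulse_offset") {
      pul <- sample.int(length(offs), nr, replace = TRUE,
                        prob = scn$per_pulse_weights)
      T0 <- T0 + offs[pul]
    }
    Tv[idx] <- T0
    Tv
  })
  blocked <- scn$reacid_blocked || is.infinite(scn$reacid$delay_s)
  q <- se <- numeric(length(t_eval))
  for (k in seq_along(t_eval)) {
    if (blocked) { q[k] <- 1; se[k] <- 0; next }
    x <- numeric(n)
    done <- T_endo <= t_eval[k]
    if (any(done)) {
      x[done] <- recovery_kernel(t_eval[k] - T_endo[done], scn$reacid)
    }
    q[k] <- 1 - (1 - s) * mean(x)
    se[k] <- (1 - s) * stats::sd(x) / sqrt(n)
  }
  data.frame(t = t_eval, q = q, se = se)
}
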