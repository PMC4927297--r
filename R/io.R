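#' Read / write a trace as CSV
#'
#' The package's on-disk trace contract: a CSV with header
#' `time_s,value,units`, time strictly increasing. Round trips are lossless
#' to 12 significant digits.
#'
#' @param path file path.
#' @return [read_trace()] returns a [timeseries()]; [write_trace()] returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(trimws(hdr), c("time_s", "value", "units"))) {
    stop("malformed header in ", path, " (line 1): expected 'time_s,value,units'")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad)) {
    stop("non-monotone time in ", path, " at line ", bad[1] + 2L)
  }
  timeseries(d$time_s, d$value, d$units[1], meta = list(path = path))
}

#' @rdname read_trace
#' @param ts a [timeseries()] to write.
#' @export
write_trace <- function(ts, path) {
  d <- data.frame(time_s = sprintf("%.12g", ts$t),
                  value = sprintf("%.12g", ts$v),
                  units = ts$units)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a scenario configuration (JSON)
#'
#' Flat key/value configuration mirroring the [scenario_params()] fields;
#' the seed is mandatory so every simulated output is reproducible.
#'
#' @param path file path.
#' @return [read_scenario()] returns a [scenario_params()];
#'   [write_scenario()] returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("scenario config must contain a seed")
  proto <- build_protocol(cfg$protocol$kind,
                          as.list(cfg$protocol$params %||% list()))
  scenario_params(
    protocol = proto,
    baseline_cm_pF = cfg$baseline_cm_pF,
    jump_total_pF = cfg$jump_total_pF,
    per_pulse_weights = cfg$per_pulse_weights,
    endo = endocytosis_params(cfg$endo$plateau_frac,
                              data.frame(fraction = cfg$endo$fraction,
                                         tau_s = cfg$endo$tau_s)),
    reacid = reacidification_params(cfg$reacid$delay_s, cfg$reacid$tau_acid_s,
                                    cfg$reacid$pH_surface %||% 7.4,
                                    cfg$reacid$pH_lumen %||% 5.5,
                                    cfg$reacid$pKa %||% 7.05,
                                    cfg$reacid$hill %||% 1),
    stranding_frac = cfg$stranding_frac %||% 0,
    reacid_blocked = isTRUE(cfg$reacid_blocked),
    surface_stranded_density = cfg$surface_stranded_density %||% 0.48,
    noise_sd = cfg$noise_sd %||% 0.03,
    bleach = list(model = cfg$bleach$model %||% "none",
                  rate = cfg$bleach$rate %||% 0),
    imaging_hz = cfg$imaging_hz %||% 0.5,
    cap_hz = cfg$cap_hz %||% 100,
    endo_start = cfg$endo_start %||% "train_end",
    t_pre_s = cfg$t_pre_s %||% 30, t_post_s = cfg$t_post_s %||% 60,
    dF_stim = cfg$dF_stim %||% 0.3,
    seed = cfg$seed, name = cfg$name %||% "custom")
}

#' @rdname read_scenario
#' @param scn a [scenario_params()] to write.
#' @export
write_scenario <- function(scn, path) {
  cfg <- list(
    name = scn$name,
    protocol = list(kind = scn$protocol$name),
    baseline_cm_pF = scn$baseline_cm_pF,
    jump_total_pF = scn$jump_total_pF,
    per_pulse_weights = scn$per_pulse_weights,
    endo = list(plateau_frac = scn$endo$plateau_frac,
                fraction = scn$endo$components$fraction,
                tau_s = scn$endo$components$tau_s),
    reacid = scn$reacid[c("delay_s", "tau_acid_s", "pH_surface", "pH_lumen",
                          "pKa", "hill")],
    stranding_frac = scn$stranding_frac,
    reacid_blocked = scn$reacid_blocked,
    surface_stranded_density = scn$surface_stranded_density,
    noise_sd = scn$noise_sd,
    bleach = scn$bleach,
    imaging_hz = scn$imaging_hz, cap_hz = scn$cap_hz,
    endo_start = scn$endo_start,
    t_pre_s = scn$t_pre_s, t_post_s = scn$t_post_s,
    dF_stim = scn$dF_stim, seed = scn$seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-pulse fluorescence drop amplitudes for widely spaced pulses.
# The de-quench recovery between pulses drifts the baseline, so the drop is
# measured against a linear extrapolation of the pre-pulse samples.
measure_fluor_jumps <- function(f, protocol, pre_s = 8, post_s = 4) {
  on_t <- protocol$pulses$onset_s
  off_t <- pulse_offsets(protocol)
  vapply(seq_along(on_t), function(i) {
    pre_i <- which(f$t >= on_t[i] - pre_s & f$t < on_t[i])
    post_i <- which(f$t > off_t[i] & f$t <= off_t[i] + post_s)
    if (length(pre_i) < 2L || !length(post_i)) {
      stop("too few imaging samples around pulse ", i)
    }
    cf <- stats::lm.fit(cbind(1, f$t[pre_i]), f$v[pre_i])$coefficients
    mean((cf[1] + cf[2] * f$t[post_i]) - f$v[post_i])
  }, numeric(1))
}

#' Run the full simulate-and-analyse replica pipeline
#'
#' For every requested preset: simulates capacitance, reporter and neighbour
#' traces, writes them (plus the state log and ground truth) under
#' `out_dir/<preset>/`, then runs the analysis stack — jump measurement,
#' endocytosis fit, quench normalisation, re-acidification fit, endpoint and
#' puff metrics — and collects everything into a machine-readable
#' `results.json`. Re-running with the same seed reproduces the outputs.
#'
#' @param presets character vector of [scenario_preset()] names.
#' @param seed integer master seed (per-preset seeds are derived from it).
#' @param out_dir output directory (created if needed).
#' @param noise_sd noise level for the simulated traces.
#' @param make_plots write per-preset PDF overlays of the normalised
#'   capacitance and quench traces.
#' @return (invisibly) the nested results list that was written to
#'   `results.json`.
#' @export
run_replica <- function(presets = c("rat_control", "dynamin", "bafilomycin",
                                    "cam_peptide", "bulk_2s", "mouse_wt",
                                    "munc13_w464r", "four_pulse"),
                        seed = 1L, out_dir = tempfile("replica"),
                        noise_sd = 0.03, make_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = seed, noise_sd = noise_sd)
  for (k in seq_along(presets)) {
    name <- presets[k]
    scn <- scenario_preset(name, seed = seed + 1000L * k, noise_sd = noise_sd)
    dir_k <- file.path(out_dir, name)
    dir.create(dir_k, showWarnings = FALSE)
    res <- tryCatch(
      replica_one(scn, dir_k, make_plots = make_plots),
      error = function(e) stop("replica stage failed for preset '", name,
                               "': ", conditionMessage(e)))
    results[[name]] <- res
  }
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

replica_one <- function(scn, dir_k, make_plots = TRUE) {
  cm <- simulate_capacitance(scn)
  rep_ <- simulate_reporter(scn, cm)
  nb <- simulate_neighbor_roi(scn)
  write_trace(cm, file.path(dir_k, "capacitance.csv"))
  write_trace(rep_$fluor, file.path(dir_k, "fluorescence.csv"))
  write_trace(nb, file.path(dir_k, "neighbor.csv"))
  utils::write.csv(rep_$state[seq(1, nrow(rep_$state), by = 25), ],
                   file.path(dir_k, "state_log.csv"), row.names = FALSE)
  write_scenario(scn, file.path(dir_k, "truth.json"))

  jumps <- measure_jumps(cm, scn$protocol)
  res <- list(jump_total_pF = jumps$total_dCm_pF,
              jump_normalized = jumps$normalized)

  if (scn$protocol$name == "four_50ms_20s") {
    dFs <- measure_fluor_jumps(rep_$fluor, scn$protocol)
    res$dF_normalized <- dFs / dFs[1]
    res$depression_ratio <- depression_ratio(jumps, dFs / dFs[1])
    return(res)
  }

  cmn <- normalize_cm(cm)
  model <- if (nrow(scn$endo$components) > 1L) "bi" else "mono"
  cfit <- fit_endocytosis(cmn, model = model)
  res$cap_fit <- list(plateau = cfit$plateau,
                      tau_s = cfit$components$tau_s,
                      amplitude_frac = cfit$components$amplitude_frac,
                      sse = cfit$sse, model = cfit$model)
  res$cm_60s <- endpoint_metric(cmn, min(60, scn$t_post_s))

  fcorr <- if (scn$bleach$model == "none") rep_$fluor else
    bleach_correct(rep_$fluor, nb, model = "auto")
  q <- normalize_invert(fcorr, mode = "delta_f")
  res$q_60s <- endpoint_metric(q, min(60, scn$t_post_s))

  rfit <- fit_reacidification(cmn, q,
                              delay_grid = seq(0, 40, by = 2),
                              tau_grid = exp(seq(log(5), log(400),
                                                 length.out = 25)))
  res$reacid_fit <- list(delay_s = rfit$delay_s,
                         tau_acid_s = rfit$tau_acid_s, sse = rfit$sse,
                         boundary = rfit$boundary,
                         unidentifiable = rfit$unidentifiable)

  puffs <- puff_events(c(-20, 40))
  if (scn$t_pre_s >= 20 && scn$t_post_s >= 46) {
    fpuff <- simulate_acid_puff(scn, rep_$state, puffs, rep_$fluor)
    pm <- puff_dequench(fpuff, puffs)
    res$puff <- list(pre_dF = pm$pre_dF / (scn$dF_stim),
                     post_dF = pm$post_dF / (scn$dF_stim),
                     ratio = pm$ratio)
  }

  if (make_plots) {
    grDevices::pdf(file.path(dir_k, "traces.pdf"), width = 6, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(cmn$t, cmn$v, type = "l", xlab = "time (s)",
                   ylab = "normalised", main = scn$name,
                   ylim = range(c(cmn$v, q$trace$v)))
    graphics::points(q$trace$t, q$trace$v, col = "red", pch = 16, cex = 0.5)
    graphics::legend("topright", c("Cm (normalised)", "quench (inverted F)"),
                     col = c("black", "red"), lty = c(1, NA),
                     pch = c(NA, 16), bty = "n")
  }
  res
}
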