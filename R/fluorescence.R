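#' Photobleaching correction against a neighbour ROI
#'
#' Fits a line or single exponential to the normalised fluorescence of a
#' neighbouring unstimulated terminal and subtracts the fitted time course
#' (minus its value at the first sample) from the target trace, scaled to
#' the target's resting intensity. `model = "auto"` fits both and keeps the
#' one with the lower sum of squared errors on the neighbour.
#'
#' @param target raw fluorescence [timeseries()] of the stimulated ROI.
#' @param neighbor raw [timeseries()] of an unstimulated neighbour sharing
#'   the illumination; must span the target (error otherwise). Resampled to
#'   the target grid if needed.
#' @param model `"linear"`, `"exponential"`, or `"auto"`.
#' @return corrected [timeseries()]; `meta$bleach_correction` records the
#'   model chosen, its parameters and neighbour sse.
#' @export
bleach_correct <- function(target, neighbor,
                           model = c("auto", "linear", "exponential")) {
  model <- match.arg(model)
  if (neighbor$t[1] > target$t[1] + 1e-9 ||
      neighbor$t[length(neighbor$t)] < target$t[length(target$t)] - 1e-9) {
    stop("neighbor trace is shorter than the target trace")
  }
  tt <- target$t
  nb <- ts_interp(neighbor, tt)
  nb0 <- mean(nb[seq_len(min(3L, length(nb)))])
  nbn <- nb / nb0
  tr <- tt - tt[1]

  fit_lin <- stats::lm.fit(cbind(1, tr), nbn)
  sse_lin <- sum(fit_lin$residuals^2)
  pred_lin <- cbind(1, tr) %*% fit_lin$coefficients

  # exponential A * exp(-r t): log-linear estimate, valid while nbn > 0
  pos <- nbn > 1e-6
  fit_exp <- stats::lm.fit(cbind(1, tr[pos]), log(nbn[pos]))
  A <- exp(fit_exp$coefficients[1]); r <- -fit_exp$coefficients[2]
  pred_exp <- A * exp(-r * tr)
  sse_exp <- sum((pred_exp - nbn)^2)

  chosen <- switch(model,
    linear = "linear", exponential = "exponential",
    auto = if (sse_exp < sse_lin) "exponential" else "linear")
  pred <- if (chosen == "linear") as.vector(pred_lin) else pred_exp

  scale0 <- mean(target$v[seq_len(min(3L, length(target$v)))])
  v <- target$v - scale0 * (pred - pred[1])
  out <- timeseries(tt, v, target$units, target$meta)
  out$meta$bleach_correction <- list(
    model = chosen,
    params = if (chosen == "linear") fit_lin$coefficients else c(A = A, rate = r),
    neighbor_sse = if (chosen == "linear") sse_lin else sse_exp)
  out
}

#' Normalise and invert a fluorescence trace into a quench trace
#'
#' Background-subtracts, normalises and inverts a raw reporter trace so
#' that 1 means "all stimulus-exposed reporter still quenched" (stimulus
#' end) and 0 means full recovery. `mode = "delta_f"` scales by the
#' stimulus-induced fluorescence drop; `mode = "initial"` first normalises
#' to the resting intensity (the two are affinely equivalent and both end at
#' 1 at the stimulus-end sample, the first imaging frame at/after t = 0).
#'
#' @param f raw fluorescence [timeseries()].
#' @param mode `"delta_f"` (default) or `"initial"`.
#' @param stim_end stimulus end time (s), default 0.
#' @param baseline_window window for the resting intensity; default all
#'   samples at least 3 s before `stim_end`.
#' @param background constant background to subtract (default 0 for
#'   synthetic traces).
#' @return object of class `quench_trace`: `trace` (a [timeseries()], units
#'   `"q_norm"`), `normalization_mode`, and `meta` (resting intensity,
#'   stimulus dF, any bleach-correction record inherited from `f`).
#' @export
normalize_invert <- function(f, mode = c("delta_f", "initial"),
                             stim_end = 0, baseline_window = NULL,
                             background = 0) {
  mode <- match.arg(mode)
  if (is.null(baseline_window)) baseline_window <- c(-Inf, stim_end - 3)
  v <- f$v - background
  base_sel <- f$t >= baseline_window[1] & f$t <= baseline_window[2]
  if (!any(base_sel)) stop("no samples in the baseline window")
  F0 <- mean(v[base_sel])
  k_end <- which(f$t >= stim_end - 1e-9)[1]
  if (is.na(k_end)) stop("no imaging sample at/after the stimulus end")
  dF <- F0 - v[k_end]
  if (dF <= 0) stop("non-positive stimulus dF (", signif(dF, 4),
                    "); trace shows no stimulus response")
  q <- (F0 - v) / dF
  tr <- timeseries(f$t, q, "q_norm", f$meta)
  structure(list(trace = tr, normalization_mode = mode,
                 meta = list(F0 = F0, dF_stim = dF,
                             stim_end_sample_s = f$t[k_end],
                             bleach_correction = f$meta$bleach_correction)),
            class = "quench_trace")
}

#' @export
print.quench_trace <- function(x, ...) {
  cat(sprintf("<quench_trace> %d samples, mode = %s, stimulus dF = %.4g\n",
              length(x$trace$t), x$normalization_mode, x$meta$dF_stim))
  invisible(x)
}

#' Acid-puff de-quench amplitudes and post/pre ratio
#'
#' For each puff, dF is the peak during the puff minus the local baseline
#' (mean of the 3 samples preceding the onset). The first puff is taken as
#' the pre-stimulus probe and the last as the post-stimulus probe; their
#' ratio reports surface-pool change (reporter stranding). Peak rather than
#' plateau is used because a 5-s puff at 0.5 Hz only yields 2-3 frames.
#'
#' @param f fluorescence [timeseries()] containing the puff transients (raw
#'   or normalised; the ratio is scale invariant).
#' @param puffs a [puff_events()] data.frame with at least 2 puffs.
#' @return object of class `puff_metrics`: `pre_dF`, `post_dF`, `ratio`
#'   (`post_dF / pre_dF`), and `all_dF`.
#' @export
puff_dequench <- function(f, puffs) {
  if (nrow(puffs) < 2L) stop("need at least a pre- and a post-stimulus puff")
  dFs <- vapply(seq_len(nrow(puffs)), function(k) {
    on <- puffs$onset_s[k]; dur <- puffs$duration_s[k]
    inwin <- which(f$t >= on - 1e-9 & f$t < on + dur - 1e-9)
    if (length(inwin) < 1L) {
      stop("puff ", k, " transient not resolvable at the sampling rate")
    }
    pre <- which(f$t < on - 1e-9)
    if (length(pre) < 3L) stop("fewer than 3 samples before puff ", k)
    max(f$v[inwin]) - mean(f$v[utils::tail(pre, 3L)])
  }, numeric(1))
  pre_dF <- dFs[1]; post_dF <- dFs[length(dFs)]
  structure(list(pre_dF = pre_dF, post_dF = post_dF,
                 ratio = if (pre_dF > 0) post_dF / pre_dF else NA_real_,
                 all_dF = dFs),
            class = "puff_metrics")
}

#' Surface and vesicular reporter densities
#'
#' Fluorescence per membrane area: the pre-stimulus acid-puff dF divided by
#' the resting capacitance gives the surface ("stranded") reporter density,
#' and the stimulus dF divided by the exocytotic jump gives the vesicular
#' density; their ratio says how much denser reporter is packed in vesicles
#' than on the surface. All inputs may be vectors (per-cell values) for
#' mean/SEM aggregation.
#'
#' @param pre_dF pre-stimulus acid-puff dF, normalised to the stimulus dF.
#' @param basal_cm_pF resting capacitance (pF).
#' @param jump_dF stimulus dF in the same normalised units (typically 1).
#' @param jump_cm_pF exocytotic capacitance jump (pF).
#' @return list with `surface_density`, `vesicular_density` (normalised
#'   dF per pF) and `ratio` (vesicular / surface).
#' @examples
#' surface_density(0.48, 18.87, 1.0, 1.52)$ratio  # ~26
#' @export
surface_density <- function(pre_dF, basal_cm_pF, jump_dF, jump_cm_pF) {
  if (any(c(pre_dF, basal_cm_pF, jump_dF, jump_cm_pF) <= 0)) {
    stop("all inputs must be > 0")
  }
  sd_ <- pre_dF / basal_cm_pF
  vd <- jump_dF / jump_cm_pF
  list(surface_density = sd_, vesicular_density = vd, ratio = vd / sd_)
}
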