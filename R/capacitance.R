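#' Measure per-pulse exocytotic capacitance jumps
#'
#' dCm per pulse is the mean over a short post-pulse window minus the mean
#' over a pre-pulse window. Defaults are a 50-ms pre window ending at pulse
#' onset and a 50-ms post window starting right at the pulse offset
#' (synthetic traces step instantaneously and carry no post-pulse artifact;
#' pass `post_skip_s = 0.05` to reproduce the artifact-avoiding 50-150 ms
#' window used on real recordings).
#'
#' @param cm capacitance [timeseries()] (pF).
#' @param protocol the [build_protocol()] that generated the trace.
#' @param window_s pre/post averaging window width (s).
#' @param post_skip_s dead time skipped after the pulse offset (s).
#' @return object of class `jump_series`: `per_pulse_dCm_pF`,
#'   `total_dCm_pF` (their sum) and `normalized` (first jump = 1).
#' @examples
#' scn <- scenario_preset("rat_control", noise_sd = 0)
#' measure_jumps(simulate_capacitance(scn), scn$protocol)$total_dCm_pF
#' @export
measure_jumps <- function(cm, protocol, window_s = 0.05, post_skip_s = 0) {
  on_t <- protocol$pulses$onset_s
  off_t <- pulse_offsets(protocol)
  if (any(on_t - window_s < cm$t[1] - 1e-9) ||
      any(off_t + post_skip_s + window_s > cm$t[length(cm$t)] + 1e-9)) {
    stop("protocol pulses (plus windows) do not fit inside the trace span")
  }
  n <- length(on_t)
  if (n > 1L) {
    post_end <- off_t + post_skip_s + window_s
    pre_start <- on_t - window_s
    clash <- which(post_end[-n] > pre_start[-1L] + 1e-9)
    if (length(clash)) {
      stop("jump windows collide between pulses ", clash[1], " and ",
           clash[1] + 1L, "; shorten window_s or post_skip_s")
    }
  }
  win_mean <- function(a, b) {
    sel <- cm$t >= a - 1e-9 & cm$t <= b + 1e-9
    if (!any(sel)) stop("no samples in window [", a, ", ", b, "] s")
    mean(cm$v[sel])
  }
  d <- vapply(seq_len(n), function(i) {
    win_mean(off_t[i] + post_skip_s, off_t[i] + post_skip_s + window_s) -
      win_mean(on_t[i] - window_s, on_t[i] - 1e-6)
  }, numeric(1))
  structure(list(per_pulse_dCm_pF = d, total_dCm_pF = sum(d),
                 normalized = d / d[1]),
            class = "jump_series")
}

#' Normalise a capacitance trace to its exocytotic jump
#'
#' Subtracts the pre-stimulus baseline and divides by the jump amplitude so
#' the recovery limb starts at 1 at t = 0 (last pulse offset) and a full
#' recovery would reach 0.
#'
#' @param cm capacitance [timeseries()] (pF).
#' @param t0 stimulus end (s), default 0.
#' @param baseline_window window for the baseline mean; default everything
#'   before the first pulse onset found in `meta`, else all `t < t0 - 5`.
#' @param jump_window optional window averaged for the jump amplitude; by
#'   default the trace value interpolated at `t0` is used (exact for
#'   noise-free traces).
#' @return normalised [timeseries()] (units `"norm"`).
#' @export
normalize_cm <- function(cm, t0 = 0, baseline_window = NULL,
                         jump_window = NULL) {
  if (is.null(baseline_window)) baseline_window <- c(-Inf, t0 - 5)
  base_sel <- cm$t >= baseline_window[1] & cm$t <= baseline_window[2]
  if (!any(base_sel)) stop("no samples in the baseline window")
  baseline <- mean(cm$v[base_sel])
  jump <- if (is.null(jump_window)) {
    ts_interp(cm, t0) - baseline
  } else {
    mean(cm$v[cm$t >= jump_window[1] & cm$t <= jump_window[2]]) - baseline
  }
  if (jump <= 0) stop("non-positive jump amplitude; cannot normalise")
  out <- timeseries(cm$t, (cm$v - baseline) / jump, "norm", cm$meta)
  out$meta$baseline_pF <- baseline
  out$meta$jump_pF <- jump
  out
}

# profiled sse for given taus: amplitudes and plateau are linear under the
# constraint y(0) = 1, via y - e_last = sum_k c_k (basis_k - e_last)
biexp_profile <- function(tt, y, taus, fit_plateau) {
  E <- vapply(taus, function(tau) exp(-tt / tau), numeric(length(tt)))
  last <- E[, ncol(E)]
  basis <- if (fit_plateau) cbind(1, E[, -ncol(E), drop = FALSE]) -
    last else E[, -ncol(E), drop = FALSE] - last
  qr_ <- qr(basis)
  if (qr_$rank < ncol(basis)) return(NULL)  # collinear (equal taus)
  cf <- qr.coef(qr_, y - last)
  res <- (y - last) - basis %*% cf
  if (fit_plateau) {
    p <- cf[1]
    amps <- c(cf[-1], 1 - sum(cf))          # coefficients on each exponential
  } else {
    p <- 0
    amps <- c(cf, 1 - sum(cf))
  }
  list(sse = sum(res^2), plateau = p, amps = amps)
}

#' Fit the endocytotic capacitance recovery
#'
#' Least-squares fit of `plateau + (1 - plateau) sum a_i exp(-t/tau_i)` to a
#' normalised recovery limb, with the time constants found by multistart
#' Nelder-Mead over a logarithmic grid and the plateau/amplitudes profiled
#' out as (constrained) linear parameters. The trace is re-normalised to its
#' value at `t_start` internally, making the fit scale-equivariant.
#'
#' @param cm normalised capacitance [timeseries()] (see [normalize_cm()]).
#' @param model `"bi"` (default) or `"mono"`.
#' @param fit_plateau keep a free non-recovered plateau (default `TRUE`).
#' @param t_start,t_end fit window (s); defaults 0 to the end of the trace.
#' @param tau_range search bounds for the time constants (s).
#' @param n_starts grid points per tau dimension for the multistart.
#' @return object of class `cap_fit`: `plateau`, `components` (data.frame
#'   `amplitude_frac`, `tau_s`, fast component first, fractions of the
#'   recoverable amplitude summing to 1), `sse`, `n_points`, `model`, and
#'   flags `tau_at_bound` / `degenerate` (bi-exponential collapsed to
#'   effectively equal taus; the fit is then reported mono-style).
#' @examples
#' scn <- scenario_preset("rat_control", noise_sd = 0)
#' cmn <- normalize_cm(simulate_capacitance(scn))
#' fit_endocytosis(cmn)$components
#' @export
fit_endocytosis <- function(cm, model = c("bi", "mono"), fit_plateau = TRUE,
                            t_start = 0, t_end = NULL,
                            tau_range = c(0.5, 500), n_starts = 5) {
  model <- match.arg(model)
  if (is.null(t_end)) t_end <- max(cm$t)
  w <- ts_window(cm, t_start, t_end)
  if (length(w$t) < 10L) stop("recovery limb has fewer than 10 samples")
  scale0 <- ts_interp(w, t_start)
  if (scale0 <= 0) stop("trace value at t_start must be positive")
  tt <- w$t - t_start
  y <- w$v / scale0
  n_tau <- if (model == "bi") 2L else 1L

  obj <- function(ltaus) {
    taus <- pmin(pmax(exp(ltaus), tau_range[1]), tau_range[2])
    pr <- biexp_profile(tt, y, taus, fit_plateau)
    if (is.null(pr)) 1e6 + sum(ltaus^2) else pr$sse
  }

  grid <- exp(seq(log(tau_range[1]), log(tau_range[2]),
                  length.out = n_starts))
  starts <- if (n_tau == 2L) {
    gg <- expand.grid(t1 = grid, t2 = grid)
    gg <- gg[gg$t1 < gg$t2, , drop = FALSE]
    lapply(seq_len(nrow(gg)), function(i) log(c(gg$t1[i], gg$t2[i])))
  } else {
    lapply(grid, log)
  }

  best <- NULL
  conv_any <- FALSE
  for (st in starts) {
    opt <- if (n_tau == 1L) {
      o <- stats::optimize(function(l) obj(l), log(tau_range), tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-14))
    }
    conv_any <- conv_any || identical(opt$convergence, 0L)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!conv_any) stop("endocytosis fit failed to converge from any start ",
                      "(best sse ", signif(best$value, 4), ")")
  if (n_tau == 2L) {
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-15))
  }

  taus <- pmin(pmax(exp(best$par), tau_range[1]), tau_range[2])
  pr <- biexp_profile(tt, y, taus, fit_plateau)
  degenerate <- FALSE
  if (is.null(pr)) {  # taus collapsed to equality: report as mono
    degenerate <- TRUE
    taus <- taus[1]
    pr <- biexp_profile(tt, y, taus, fit_plateau)
    n_tau <- 1L
  }
  rec <- 1 - pr$plateau
  amp_frac <- if (abs(rec) < 1e-12) rep(1 / n_tau, n_tau) else pr$amps / rec
  o <- order(taus)
  comp <- data.frame(amplitude_frac = amp_frac[o], tau_s = taus[o])
  if (n_tau == 2L && abs(diff(taus)) < 1e-3 * mean(taus)) degenerate <- TRUE
  tau_at_bound <- any(taus <= tau_range[1] * 1.001) ||
    any(taus >= tau_range[2] * 0.999)
  structure(list(plateau = pr$plateau, components = comp, sse = pr$sse,
                 n_points = length(y),
                 model = if (n_tau == 2L) "bi" else "mono",
                 tau_at_bound = tau_at_bound, degenerate = degenerate),
            class = "cap_fit")
}

#' @export
print.cap_fit <- function(x, ...) {
  cat(sprintf("<cap_fit> %s-exponential, plateau %.4g, sse %.3g (n = %d)\n",
              x$model, x$plateau, x$sse, x$n_points))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  tau = %.4g s (%.1f%% of recoverable)\n",
                x$components$tau_s[i], 100 * x$components$amplitude_frac[i]))
  }
  if (x$tau_at_bound) cat("  WARNING: tau at search bound\n")
  if (x$degenerate) cat("  note: bi-exponential degenerate (equal taus)\n")
  invisible(x)
}

#' Normalised trace value at a given time
#'
#' Linear interpolation between the two nearest samples; the standard
#' endpoint metric (e.g. normalised Cm or quench value 60 s after the
#' stimulus).
#'
#' @param x a [timeseries()] or `quench_trace`.
#' @param t_s time (s); must lie within the trace span.
#' @return interpolated value.
#' @export
endpoint_metric <- function(x, t_s) {
  ts <- if (inherits(x, "quench_trace")) x$trace else x
  ts_interp(ts, t_s)
}
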