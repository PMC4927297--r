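#' Henderson-Hasselbalch fluorescence of the reporter
#'
#' Relative fluorescence of the pH-sensitive reporter as a function of pH.
#' The protonated (acidic) form is fluorescent, so
#' `phi(pH) = 1 / (1 + 10^(hill * (pH - pKa)))`: close to 1 at the vesicular
#' pH 5.5 and mostly quenched at the extracellular pH 7.4.
#'
#' @param pH numeric vector of pH values.
#' @param params a [reacidification_params()] object supplying `pKa` and
#'   `hill` (defaults 7.05 and 1).
#' @return relative fluorescence in (0, 1), same length as `pH`.
#' @examples
#' p <- reacidification_params(14, 38.7)
#' hh_fluorescence(7.05, p)  # 0.5 at the pKa
#' @export
hh_fluorescence <- function(pH, params = reacidification_params(0, 1)) {
  1 / (1 + 10^(params$hill * (pH - params$pKa)))
}

#' Organelle recovery (de-quench) kernel
#'
#' Fractional fluorescence recovery of a single organelle `s` seconds after
#' its membrane was retrieved. The lumen stays at the extracellular pH for
#' `delay_s`, then re-acidifies exponentially from `pH_surface` to
#' `pH_lumen` with time constant `tau_acid_s`; the pH course is mapped
#' through [hh_fluorescence()] and normalised so the kernel runs from 0
#' (just retrieved, still neutral) to 1 (fully re-acidified).
#'
#' @param s time since membrane retrieval (s, >= 0), vectorised.
#' @param params a [reacidification_params()] object.
#' @return `g(s)` in `[0, 1]`, non-decreasing in `s`.
#' @export
recovery_kernel <- function(s, params) {
  g <- numeric(length(s))
  if (is.infinite(params$delay_s)) return(g)
  act <- s >= params$delay_s
  if (any(act)) {
    pH <- params$pH_lumen + (params$pH_surface - params$pH_lumen) *
      exp(-(s[act] - params$delay_s) / params$tau_acid_s)
    num <- hh_fluorescence(pH, params) - hh_fluorescence(params$pH_surface, params)
    den <- hh_fluorescence(params$pH_lumen, params) -
      hh_fluorescence(params$pH_surface, params)
    g[act] <- num / den
  }
  g
}

# discrete causal convolution dt * sum_{j<=k} e_j g_{k-j}, trapezoid-corrected.
# e and g sampled on the same uniform grid starting at t = 0.
conv_flux_kernel <- function(e, g, dt) {
  n <- length(e)
  z <- stats::convolve(e, rev(g), type = "open")[seq_len(n)]
  # trapezoid end correction; g[1] = g(0) = 0 for any admissible kernel
  dt * (z - 0.5 * (e[1] * g + e * g[1]))
}

# resample the normalized capacitance recovery onto a uniform grid from t = 0,
# enforce a non-increasing limb (isotonic), and differentiate to get the
# endocytic flux e(t) (clipped at 0). Returns list(t, cm, e, dt).
prepare_flux <- function(cm_norm, dt_s = 0.25, smooth = TRUE) {
  t_max <- max(cm_norm$t)
  if (t_max <= dt_s * 10) stop("recovery limb too short for flux estimation")
  tg <- seq(0, t_max, by = dt_s)
  v <- ts_interp(cm_norm, tg)
  if (smooth) {
    iso <- stats::isoreg(tg, -v)   # non-increasing fit of the recovery limb
    v <- -iso$yf
  }
  n <- length(v)
  e <- numeric(n)
  e[2:(n - 1)] <- (v[1:(n - 2)] - v[3:n]) / (2 * dt_s)
  e[1] <- (v[1] - v[2]) / dt_s
  e[n] <- (v[n - 1] - v[n]) / dt_s
  e[e < 0] <- 0
  list(t = tg, cm = v, e = e, dt = dt_s)
}

#' Predict the reporter quench trace from a capacitance recovery
#'
#' The forward (convolution) model at the heart of the package: the
#' endocytic flux is the negative time derivative of the normalised
#' capacitance recovery, and each endocytosed parcel de-quenches according
#' to the organelle recovery kernel, so
#' `Q(t) = 1 - integral_0^t e(t') g(t - t') dt'`.
#'
#' @param cm_norm capacitance trace normalised to the jump (1 at t = 0, the
#'   stimulus end); only `t >= 0` is used. Non-monotone segments are tamed by
#'   isotonic regression before differentiation.
#' @param params a [reacidification_params()] object.
#' @param mode `"per_organelle"`: the kernel itself carries the onset delay
#'   (each organelle stays neutral for `delay_s` after its own retrieval).
#'   `"global_delay"`: the delay-free convolution is computed and the whole
#'   curve is held at 1 for `delay_s`, then time-shifted — the reading in
#'   which the fitted curve "was held to be 1" during the delay. The two
#'   modes coincide when all endocytosis occurs at the stimulus end.
#' @param dt_s grid step for differentiation and quadrature (s).
#' @param stranding_frac fraction of reporter never co-retrieved; scales the
#'   recoverable part: `Q = s + (1 - s) (1 - conv)`.
#' @return a [timeseries()] of the predicted quench trace on the internal
#'   grid (units `"q_norm"`), with `meta$nonmonotone_warning` set if the
#'   input recovery limb rose by more than 2% of its range.
#' @export
predict_quench <- function(cm_norm, params,
                           mode = c("per_organelle", "global_delay"),
                           dt_s = 0.25, stranding_frac = 0) {
  mode <- match.arg(mode)
  cmp <- ts_window(cm_norm, 0, Inf)
  rises <- diff(cmp$v)
  nonmono <- sum(rises[rises > 0]) > 0.02 * diff(range(cmp$v))
  fl <- prepare_flux(cmp, dt_s = dt_s)
  if (mode == "per_organelle") {
    g <- recovery_kernel(fl$t, params)
    acid <- conv_flux_kernel(fl$e, g, fl$dt)
  } else {
    p0 <- params
    p0$delay_s <- 0
    g <- recovery_kernel(fl$t, p0)
    acid0 <- conv_flux_kernel(fl$e, g, fl$dt)
    if (is.infinite(params$delay_s)) {
      acid <- numeric(length(fl$t))
    } else {
      acid <- stats::approx(fl$t + params$delay_s, acid0, xout = fl$t,
                            yleft = 0, rule = 2)$y
    }
  }
  q <- stranding_frac + (1 - stranding_frac) * (1 - pmin(pmax(acid, 0), 1))
  timeseries(fl$t, q, "q_norm",
             meta = list(mode = mode, dt_s = dt_s,
                         delay_s = params$delay_s,
                         tau_acid_s = params$tau_acid_s,
                         nonmonotone_warning = nonmono))
}

#' Fit re-acidification delay and time constant by least squares
#'
#' Recovers `(delay, tau_acid)` by exhaustively scanning a grid of the
#' convolution model's sum of squared errors against an observed quench
#' trace, then polishing the grid minimum with a Nelder-Mead refinement on
#' `(delay, log tau)`. The full sse surface is retained for diagnostics.
#'
#' @param cm_norm normalised capacitance trace (1 at t = 0) from the same
#'   cell/scenario as `q`.
#' @param q observed quench trace: a `quench_trace` from
#'   [normalize_invert()] or any [timeseries()] on the quench scale.
#' @param delay_grid delays to scan (s); default 0..40 s in 1-s steps.
#' @param tau_grid time constants to scan (s); default 40 log-spaced values
#'   in 5..200 s.
#' @param mode forwarded to [predict_quench()].
#' @param dt_s forward-model grid step (s).
#' @param refine polish the grid minimum (logical).
#' @return object of class `reacid_fit`: `delay_s`, `tau_acid_s`, `sse`,
#'   `grid_surface` (data.frame `delay_s`, `tau_s`, `sse`), `mode`,
#'   `boundary` (minimum at the edge of the searched region) and
#'   `unidentifiable` (flat sse surface, e.g. a non-recovering trace).
#' @export
fit_reacidification <- function(cm_norm, q,
                                delay_grid = seq(0, 40, by = 1),
                                tau_grid = exp(seq(log(5), log(200),
                                                   length.out = 40)),
                                mode = c("per_organelle", "global_delay"),
                                dt_s = 0.25, refine = TRUE) {
  mode <- match.arg(mode)
  qt <- if (inherits(q, "quench_trace")) q$trace else q
  qt <- ts_window(qt, 0, Inf)
  cmp <- ts_window(cm_norm, 0, Inf)
  t_max <- min(max(qt$t), max(cmp$t))
  qt <- ts_window(qt, 0, t_max)
  fl <- prepare_flux(ts_window(cmp, 0, t_max), dt_s = dt_s)
  # map q sample times onto the model grid once
  idx <- stats::approx(fl$t, seq_along(fl$t), xout = pmin(qt$t, max(fl$t)))$y
  lo <- floor(idx); hi <- ceiling(idx); w <- idx - lo

  sse_of <- function(delay, tau) {
    par <- reacidification_params(delay_s = delay, tau_acid_s = tau)
    if (mode == "per_organelle") {
      g <- recovery_kernel(fl$t, par)
      acid <- conv_flux_kernel(fl$e, g, fl$dt)
    } else {
      par0 <- par; par0$delay_s <- 0
      g <- recovery_kernel(fl$t, par0)
      acid0 <- conv_flux_kernel(fl$e, g, fl$dt)
      acid <- stats::approx(fl$t + delay, acid0, xout = fl$t,
                            yleft = 0, rule = 2)$y
    }
    qm <- 1 - pmin(pmax(acid, 0), 1)
    pred <- qm[lo] * (1 - w) + qm[hi] * w
    sum((pred - qt$v)^2)
  }

  surface <- expand.grid(delay_s = delay_grid, tau_s = tau_grid)
  surface$sse <- mapply(sse_of, surface$delay_s, surface$tau_s)
  best <- which.min(surface$sse)
  d0 <- surface$delay_s[best]
  tau0 <- surface$tau_s[best]
  sse0 <- surface$sse[best]

  rng <- max(surface$sse) - min(surface$sse)
  unident <- !is.finite(rng) || rng < 1e-10 ||
    rng < 1e-6 * max(1e-12, min(surface$sse)) ||
    stats::sd(qt$v) < 1e-9

  d_lim <- range(delay_grid); tau_lim <- range(tau_grid)
  if (refine && !unident) {
    obj <- function(p) {
      d <- min(max(p[1], d_lim[1]), d_lim[2])
      tau <- min(max(exp(p[2]), tau_lim[1]), tau_lim[2])
      sse_of(d, tau)
    }
    opt <- stats::optim(c(d0, log(tau0)), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12))
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12))
    d0 <- min(max(opt$par[1], d_lim[1]), d_lim[2])
    tau0 <- min(max(exp(opt$par[2]), tau_lim[1]), tau_lim[2])
    sse0 <- opt$value
  }

  eps_d <- diff(d_lim) * 1e-3
  boundary <- unident ||
    d0 <= d_lim[1] + eps_d && d_lim[1] > 0 || d0 >= d_lim[2] - eps_d ||
    tau0 <= tau_lim[1] * 1.001 || tau0 >= tau_lim[2] * 0.999

  structure(list(delay_s = d0, tau_acid_s = tau0, sse = sse0,
                 grid_surface = surface, mode = mode,
                 boundary = boundary, unidentifiable = unident,
                 n_points = length(qt$v)),
            class = "reacid_fit")
}

#' @export
print.reacid_fit <- function(x, ...) {
  cat(sprintf("<reacid_fit> delay %.2f s, tau_acid %.2f s (sse %.3g, %s mode)\n",
              x$delay_s, x$tau_acid_s, x$sse, x$mode))
  if (x$unidentifiable) cat("  WARNING: sse surface flat - parameters unidentifiable\n")
  else if (x$boundary) cat("  WARNING: minimum on the grid boundary\n")
  invisible(x)
}

#' Delayed single-exponential fit of a quench recovery
#'
#' Descriptive fit used for long recordings:
#' `Q(t) = A + (1 - A) min(1, exp(-(t - d)/tau))`, i.e. the trace is held at
#' 1 until the delay `d` and then relaxes exponentially towards the
#' asymptote `A`. The delay is scanned on a grid; for each delay the
#' time constant is optimised in 1-D with the asymptote solved in closed
#' form (linear least squares given the exponential).
#'
#' @param q a `quench_trace` or [timeseries()] on the quench scale.
#' @param asymptote `"free"` (default) or `"fixed"` (at `A_fixed`).
#' @param A_fixed asymptote value when `asymptote = "fixed"`.
#' @param delay_grid candidate delays (s); defaults to the sample grid up to
#'   half the recording span (capped at 40 s).
#' @param tau_range search range for the time constant (s).
#' @return list with `delay_s`, `tau_s`, `asymptote`, `sse`, and
#'   `tau_at_bound` (TRUE when the time constant ran into `tau_range`, e.g.
#'   for a non-recovering trace).
#' @export
fit_delayed_exponential <- function(q, asymptote = c("free", "fixed"),
                                    A_fixed = NULL, delay_grid = NULL,
                                    tau_range = c(1, 1000)) {
  asymptote <- match.arg(asymptote)
  if (asymptote == "fixed" && is.null(A_fixed)) stop("A_fixed required")
  qt <- if (inherits(q, "quench_trace")) q$trace else q
  qt <- ts_window(qt, 0, Inf)
  if (length(qt$t) < 10L) stop("recovery limb has fewer than 10 samples")
  if (is.null(delay_grid)) {
    delay_grid <- qt$t[qt$t <= min(40, max(qt$t) / 2)]
  }

  fit_for_delay <- function(d) {
    s <- pmax(qt$t - d, 0)
    sse_tau <- function(ltau) {
      E <- exp(-s / exp(ltau))   # = 1 for t < d (held at 1)
      if (asymptote == "free") {
        den <- sum((1 - E)^2)
        A <- if (den < 1e-12) 0 else sum((qt$v - E) * (1 - E)) / den
        A <- min(max(A, -0.5), 1)
      } else A <- A_fixed
      sum((A + (1 - A) * E - qt$v)^2)
    }
    o <- stats::optimize(sse_tau, log(tau_range), tol = 1e-10)
    ltau <- o$minimum
    E <- exp(-s / exp(ltau))
    if (asymptote == "free") {
      den <- sum((1 - E)^2)
      A <- if (den < 1e-12) 0 else sum((qt$v - E) * (1 - E)) / den
      A <- min(max(A, -0.5), 1)
    } else A <- A_fixed
    list(tau = exp(ltau), A = A, sse = o$objective)
  }

  fits <- lapply(delay_grid, fit_for_delay)
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  k <- which.min(sses)
  best <- fits[[k]]
  tau_at_bound <- best$tau <= tau_range[1] * 1.01 ||
    best$tau >= tau_range[2] * 0.99
  list(delay_s = delay_grid[k], tau_s = best$tau, asymptote = best$A,
       sse = best$sse, tau_at_bound = tau_at_bound)
}
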