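#' Construct a time series trace
#'
#' Light S3 container used throughout the package for capacitance and
#' fluorescence traces. Time is in seconds with t = 0 at the offset of the
#' last stimulus pulse (recorded in `meta$t0`), values are in the units given
#' (`"pF"` for capacitance, `"au"` or `"dF_norm"` for fluorescence).
#'
#' @param t numeric vector of sample times (s), strictly increasing.
#' @param v numeric vector of values, same length as `t`.
#' @param units single non-empty string.
#' @param meta named list of provenance fields (scenario name, seed, t0
#'   convention, ...).
#' @return An object of class `calyx_ts` with fields `t`, `v`, `units`,
#'   `meta`.
#' @export
timeseries <- function(t, v, units, meta = list()) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) stop("t and v must have the same length")
  if (length(t) < 2L) stop("a trace needs at least 2 samples")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("units must be a single non-empty string")
  }
  structure(list(t = t, v = v, units = units, meta = meta),
            class = "calyx_ts")
}

#' @export
print.calyx_ts <- function(x, ...) {
  cat(sprintf("<calyx_ts> %d samples, t = [%.3g, %.3g] s, units = %s\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$units))
  if (!is.null(x$meta$scenario)) cat("  scenario:", x$meta$scenario, "\n")
  invisible(x)
}

#' @export
as.data.frame.calyx_ts <- function(x, ...) {
  data.frame(time_s = x$t, value = x$v, units = x$units,
             stringsAsFactors = FALSE)
}

#' Linear interpolation of a trace
#'
#' @param ts a [timeseries()] object.
#' @param t_out times (s) at which to evaluate; must lie within the span.
#' @return numeric vector of interpolated values.
#' @export
ts_interp <- function(ts, t_out) {
  if (any(t_out < ts$t[1] - 1e-9) || any(t_out > ts$t[length(ts$t)] + 1e-9)) {
    stop("requested time outside trace span [",
         ts$t[1], ", ", ts$t[length(ts$t)], "] s")
  }
  stats::approx(ts$t, ts$v, xout = t_out, rule = 2)$y
}

#' Restrict a trace to a time window
#'
#' @param ts a [timeseries()] object.
#' @param t_min,t_max window bounds in seconds (inclusive).
#' @return a [timeseries()] restricted to `[t_min, t_max]`.
#' @export
ts_window <- function(ts, t_min = -Inf, t_max = Inf) {
  keep <- ts$t >= t_min - 1e-12 & ts$t <= t_max + 1e-12
  if (sum(keep) < 2L) stop("window [", t_min, ", ", t_max, "] retains < 2 samples")
  timeseries(ts$t[keep], ts$v[keep], ts$units, ts$meta)
}

# run code with a temporary RNG state seeded from `seed`; global state restored
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
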