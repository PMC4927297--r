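#' Group summary as mean and standard error
#'
#' @param values numeric vector (n >= 1).
#' @param label group label.
#' @return object of class `group_summary`: `label`, `n`, `mean`, `sem`
#'   (sd with n - 1 denominator over sqrt(n); 0 for n = 1), `values`.
#' @export
mean_sem <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty input")
  n <- length(values)
  sem <- if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  structure(list(label = label, n = n, mean = mean(values), sem = sem,
                 values = values),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$label, x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-sided Student's t test
#'
#' Classic pooled-variance Student test (the paper-style default); set
#' `welch = TRUE` for the unequal-variance variant. Paired tests require
#' equal group sizes.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param paired logical.
#' @param welch use Welch's correction instead of pooled variance.
#' @return list with `t`, `p`, `df`.
#' @export
t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (paired && length(a) != length(b)) stop("paired test needs equal n")
  if (paired) {
    if (stats::sd(a - b) < 1e-300 && !all(a == b)) stop("degenerate variance")
    if (all(a == b)) return(list(t = 0, p = 1, df = length(a) - 1L))
  } else if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = length(a) + length(b) - 2L))
    stop("degenerate variance: groups are constants")
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = !welch && !paired)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Ratio of normalised capacitance and fluorescence depression
#'
#' For a depression series (e.g. four pulses 20 s apart), divides the
#' first-normalised dCm amplitudes by the first-normalised dF amplitudes
#' per stimulus. Ratios near 1 across the train mean membrane and reporter
#' report the same exocytosis (homogeneous labelling).
#'
#' @param jumps a `jump_series` from [measure_jumps()] (its `normalized`
#'   field) or a numeric vector already normalised to the first amplitude.
#' @param dFs fluorescence amplitudes normalised to the first (same length).
#' @return numeric vector of per-stimulus ratios.
#' @export
depression_ratio <- function(jumps, dFs) {
  jn <- if (inherits(jumps, "jump_series")) jumps$normalized else as.numeric(jumps)
  dFs <- as.numeric(dFs)
  if (length(jn) != length(dFs) || length(jn) < 2L) {
    stop("need equal-length series with at least 2 stimuli")
  }
  if (any(dFs == 0)) stop("zero dF amplitude in the series")
  jn / dFs
}
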