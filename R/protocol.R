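#' Build a stimulation protocol
#'
#' Returns the pulse timing of one of the named depolarisation paradigms.
#' Times follow the package convention that t = 0 sits at the offset of the
#' last pulse, so all onsets are negative; recovery fits and quench
#' normalisation anchor there.
#'
#' @param kind one of `"train_10x50ms"` (ten 50-ms pulses, 200-ms
#'   interstimulus interval, i.e. onsets 250 ms apart), `"single_2s"` (one
#'   prolonged 2-s pulse), `"four_50ms_20s"` (four 50-ms pulses with 20-s
#'   onset spacing).
#' @param params optional overrides: `n_pulses`, `duration_s`, `interval_s`
#'   (onset-to-onset spacing).
#' @return An object of class `stim_protocol`: a list with `pulses`
#'   (data.frame `onset_s`, `duration_s`), `name`, and `meta` recording the
#'   pulse/interval convention.
#' @examples
#' p <- build_protocol("train_10x50ms")
#' nrow(p$pulses)  # 10
#' @export
build_protocol <- function(kind, params = list()) {
  defaults <- switch(kind,
    train_10x50ms = list(n_pulses = 10L, duration_s = 0.05, interval_s = 0.25),
    single_2s     = list(n_pulses = 1L,  duration_s = 2,    interval_s = 0),
    four_50ms_20s = list(n_pulses = 4L,  duration_s = 0.05, interval_s = 20),
    stop("unknown protocol kind: '", kind,
         "' (expected train_10x50ms, single_2s or four_50ms_20s)")
  )
  p <- utils::modifyList(defaults, params)
  onsets <- (seq_len(p$n_pulses) - 1L) * p$interval_s
  # shift so the last pulse offset is t = 0
  onsets <- onsets - (onsets[p$n_pulses] + p$duration_s)
  pulses <- data.frame(onset_s = onsets, duration_s = p$duration_s)
  validate_protocol(structure(
    list(pulses = pulses, name = kind,
         meta = list(interval_s = p$interval_s,
                     convention = "onset spacing = pulse + interstimulus interval; t0 = last pulse offset")),
    class = "stim_protocol"))
}

validate_protocol <- function(x) {
  p <- x$pulses
  if (any(p$duration_s <= 0)) stop("pulse durations must be > 0")
  if (nrow(p) > 1L) {
    if (any(diff(p$onset_s) <= 0)) stop("pulse onsets must be strictly increasing")
    if (any(p$onset_s[-1L] < (p$onset_s + p$duration_s)[-nrow(p)])) {
      stop("pulses overlap")
    }
  }
  x
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %s: %d pulse(s), offsets %s s\n", x$name,
              nrow(x$pulses),
              paste(signif(x$pulses$onset_s + x$pulses$duration_s, 4), collapse = ", ")))
  invisible(x)
}

# pulse offset times (s), the instants at which exocytotic steps occur
pulse_offsets <- function(protocol) {
  protocol$pulses$onset_s + protocol$pulses$duration_s
}

#' Define extracellular acid puff events
#'
#' Brief extracellular applications of acidic solution (default pH 5.5 for
#' 5 s) that transiently de-quench surface-exposed reporter, probing the
#' surface pool before and after stimulation.
#'
#' @param onset_s numeric vector of puff onsets (s, t = 0 at last pulse
#'   offset).
#' @param duration_s puff duration(s), recycled; default 5 s.
#' @param pH puff solution pH, recycled; default 5.5.
#' @return data.frame of class `puff_events` with columns `onset_s`,
#'   `duration_s`, `pH`.
#' @export
puff_events <- function(onset_s, duration_s = 5, pH = 5.5) {
  d <- data.frame(onset_s = onset_s, duration_s = duration_s, pH = pH)
  if (any(d$duration_s <= 0)) stop("puff durations must be > 0")
  d <- d[order(d$onset_s), , drop = FALSE]
  if (nrow(d) > 1L &&
      any(d$onset_s[-1L] < (d$onset_s + d$duration_s)[-nrow(d)] - 1e-9)) {
    stop("puff events overlap")
  }
  class(d) <- c("puff_events", "data.frame")
  d
}
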