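#' Burst-stimulation protocol
#'
#' Describes the electrical stimulation delivered to the midbrain: one or more
#' bursts of pulses at a fixed frequency and constant current. The defaults
#' are the standard single-burst paradigm: 30 pulses at 50 Hz (a 0.6 s burst)
#' at 0.4 mA, starting 2 s into the recording.
#'
#' @param n_pulses pulses per burst (integer, >= 1)
#' @param frequency_hz pulse frequency within a burst, Hz (> 0)
#' @param current_ma stimulation current, mA (>= 0)
#' @param onset_s start time of the first burst, s (>= 0)
#' @param n_bursts number of bursts (integer, >= 1)
#' @param inter_burst_interval_s onset-to-onset spacing between consecutive
#'   bursts, s; required when `n_bursts > 1` and must be at least one burst
#'   duration so bursts do not overlap
#' @return an object of class `stim_protocol`
#' @examples
#' p <- stim_protocol()
#' burst_duration(p) # 0.6 s
#' @export
stim_protocol <- function(n_pulses = 30L, frequency_hz = 50, current_ma = 0.4,
                          onset_s = 2, n_bursts = 1L,
                          inter_burst_interval_s = NULL) {
  p <- structure(
    list(n_pulses = as.integer(n_pulses), frequency_hz = as.numeric(frequency_hz),
         current_ma = as.numeric(current_ma), onset_s = as.numeric(onset_s),
         n_bursts = as.integer(n_bursts),
         inter_burst_interval_s = if (is.null(inter_burst_interval_s)) NULL
                                  else as.numeric(inter_burst_interval_s)),
    class = "stim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  if (!inherits(p, "stim_protocol"))
    stop("invalid stimulus protocol: not a stim_protocol object")
  bad <- function(msg) stop("invalid stimulus protocol: ", msg, call. = FALSE)
  if (length(p$n_pulses) != 1L || is.na(p$n_pulses) || p$n_pulses < 1L)
    bad("n_pulses must be an integer >= 1")
  if (length(p$frequency_hz) != 1L || !is.finite(p$frequency_hz) || p$frequency_hz <= 0)
    bad("frequency_hz must be > 0")
  if (length(p$current_ma) != 1L || !is.finite(p$current_ma) || p$current_ma < 0)
    bad("current_ma must be >= 0")
  if (length(p$onset_s) != 1L || !is.finite(p$onset_s) || p$onset_s < 0)
    bad("onset_s must be >= 0")
  if (length(p$n_bursts) != 1L || is.na(p$n_bursts) || p$n_bursts < 1L)
    bad("n_bursts must be an integer >= 1")
  if (p$n_bursts > 1L) {
    if (is.null(p$inter_burst_interval_s) || !is.finite(p$inter_burst_interval_s))
      bad("inter_burst_interval_s is required when n_bursts > 1")
    if (p$inter_burst_interval_s < burst_duration(p))
      bad("bursts overlap: inter_burst_interval_s must be >= n_pulses/frequency_hz")
  }
  invisible(p)
}

#' Duration of a single burst
#'
#' @param protocol a [stim_protocol()]
#' @return burst length `n_pulses / frequency_hz`, s
#' @export
burst_duration <- function(protocol) {
  protocol$n_pulses / protocol$frequency_hz
}

#' Onset times of every burst
#'
#' @param protocol a [stim_protocol()]
#' @return numeric vector of burst start times, s
#' @export
burst_onsets <- function(protocol) {
  if (protocol$n_bursts == 1L) return(protocol$onset_s)
  protocol$onset_s +
    (seq_len(protocol$n_bursts) - 1L) * protocol$inter_burst_interval_s
}

#' End time of the stimulation
#'
#' @param protocol a [stim_protocol()]
#' @return offset of the last burst, s
#' @export
protocol_end <- function(protocol) {
  max(burst_onsets(protocol)) + burst_duration(protocol)
}

#' Stimulus envelope
#'
#' The pulse-train indicator: 1 while a burst is being delivered, 0 otherwise.
#' Each burst spans the closed window from its onset to onset +
#' `n_pulses/frequency_hz` (the Heaviside step is taken as 1 at 0, so both
#' window endpoints are inside the burst).
#'
#' @param t time or vector of times, s (>= 0)
#' @param protocol a [stim_protocol()]
#' @return integer vector of 0/1 the same length as `t`
#' @examples
#' p <- stim_protocol(onset_s = 1)
#' stimulus_envelope(c(0, 1.3, 2), p) # 0 1 0
#' @export
stimulus_envelope <- function(t, protocol) {
  validate_protocol(protocol)
  if (any(!is.finite(t)) || any(t < 0))
    stop("stimulus_envelope: t must be finite and >= 0")
  on <- burst_onsets(protocol)
  dur <- burst_duration(protocol)
  out <- integer(length(t))
  for (t0 in on) out <- out | (t >= t0 & t <= t0 + dur)
  as.integer(out)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol: %d burst(s) of %d pulses at %g Hz (%.3g s), %g mA\n",
              x$n_bursts, x$n_pulses, x$frequency_hz, burst_duration(x),
              x$current_ma))
  cat(sprintf("  first onset at t = %g s\n", x$onset_s))
  invisible(x)
}
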