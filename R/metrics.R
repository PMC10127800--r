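#' Evoked peak amplitude of a recording
#'
#' Baseline is the mean of all samples before the stimulus onset; the peak is
#' the maximum baseline-subtracted signal at or after onset, with ties broken
#' by the earliest time.
#'
#' @param rec an [fscv_recording()]
#' @param protocol the [stim_protocol()] used during acquisition
#' @return a list with `amplitude` (uM), `peak_time` (s) and `baseline` (uM)
#' @export
peak_amplitude <- function(rec, protocol) {
  stopifnot(inherits(rec, "fscv_recording"))
  validate_protocol(protocol)
  pre <- rec$time < protocol$onset_s
  if (!any(pre))
    stop("peak_amplitude: baseline undefined, no samples before stimulus onset")
  baseline <- mean(rec$da[pre])
  post <- which(rec$time >= protocol$onset_s)
  excess <- rec$da[post] - baseline
  i <- post[which.max(excess)]  # which.max takes the first maximum
  list(amplitude = max(excess), peak_time = rec$time[i], baseline = baseline)
}

#' Clearance half-time of an evoked dopamine transient
#'
#' Time from the evoked peak until the signal first falls to 50% of the peak
#' above baseline. The crossing is located by linear interpolation between the
#' two samples bracketing the first downward crossing of
#' `baseline + 0.5 * (peak - baseline)`.
#'
#' @inheritParams peak_amplitude
#' @return half-time, s
#' @examples
#' # linear decay from 1 uM at t = 2 s to 0 uM at t = 4 s: t1/2 = 1 s
#' @export
clearance_half_time <- function(rec, protocol) {
  pk <- peak_amplitude(rec, protocol)
  if (pk$amplitude <= 0)
    stop("clearance_half_time: no evoked peak above baseline")
  thr <- pk$baseline + 0.5 * pk$amplitude
  after <- which(rec$time >= pk$peak_time)
  below <- which(rec$da[after] < thr)
  if (!length(below))
    stop("clearance_half_time: signal never decays to half-peak within the recording")
  j <- after[below[1L]]          # first sample strictly below threshold
  i <- j - 1L                    # bracketing sample at or above threshold
  t_cross <- rec$time[i] +
    (thr - rec$da[i]) / (rec$da[j] - rec$da[i]) * (rec$time[j] - rec$time[i])
  t_cross - pk$peak_time
}

#' Coefficient of determination between two recordings
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean. Equals 1 iff the prediction reproduces the observation
#' exactly; a constant observed signal has no defined R-squared.
#'
#' @param observed an [fscv_recording()] or numeric vector
#' @param predicted an [fscv_recording()] or numeric vector on the same grid
#' @return R-squared (dimensionless, <= 1)
#' @export
r_squared <- function(observed, predicted) {
  if (inherits(observed, "fscv_recording") && inherits(predicted, "fscv_recording")) {
    if (length(observed$time) != length(predicted$time) ||
        any(abs(observed$time - predicted$time) > 1e-9))
      stop("r_squared: recordings are not on identical time grids")
    observed <- observed$da; predicted <- predicted$da
  }
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("r_squared: undefined for a constant observed signal (SS_tot = 0)")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test of two groups of trace metrics (e.g. per-animal
#' clearance half-times), with the Welch-Satterthwaite degrees of freedom and
#' a two-sided p value.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2; at least one
#'   group must have nonzero variance
#' @return a list with `t`, `df`, `p`, and the group means
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("welch_t: insufficient data, each group needs >= 2 values")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("welch_t: both groups have zero variance")
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' All trace summary metrics at once
#'
#' @inheritParams peak_amplitude
#' @return a one-row data.frame with `peak_um`, `peak_time_s`, `t_half_s`,
#'   `baseline_um`; `t_half_s` is `NA` when the signal never reaches half-peak
#' @export
trace_metrics <- function(rec, protocol) {
  pk <- peak_amplitude(rec, protocol)
  th <- tryCatch(clearance_half_time(rec, protocol),
                 error = function(e) NA_real_)
  data.frame(peak_um = pk$amplitude, peak_time_s = pk$peak_time,
             t_half_s = th, baseline_um = pk$baseline)
}
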