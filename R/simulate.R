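#' Michaelis-Menten reuptake rate
#'
#' Velocity of dopamine clearance by the dopamine transporter at a given
#' striatal dopamine concentration: `Vm * da_s / (da_s + Km)`. Monotone
#' nondecreasing in `da_s` and bounded above by `Vm`.
#'
#' @param da_s striatal dopamine concentration(s), uM (>= 0)
#' @param params a [kinetic_params()]
#' @return reuptake velocity, uM/s
#' @examples
#' reuptake_rate(0.2, wt_params()) # half-saturation: Vm/2
#' @export
reuptake_rate <- function(da_s, params) {
  validate_params(params)
  if (any(!is.finite(da_s)) || any(da_s < 0))
    stop("reuptake_rate: da_s must be finite and >= 0")
  params$Vm * da_s / (da_s + params$Km)
}

new_conc_trace <- function(time, DA_S, DA_E, Gamma_DA, dt) {
  structure(list(time = time, DA_S = DA_S, DA_E = DA_E,
                 Gamma_DA = Gamma_DA, dt = dt),
            class = "conc_trace")
}

## Integrate the three-state system from an arbitrary initial state.
## Internal: the exported simulate_trace() fixes the zero initial state.
## The release source is piecewise constant: it is sampled at the midpoint of
## every RK4 step, and burst boundaries are required to fall on grid nodes, so
## each step sees a genuinely constant source.
simulate_from_state <- function(params, protocol, duration, dt = 1e-3,
                                init_state = c(0, 0, 0)) {
  validate_params(params)
  validate_protocol(protocol)
  if (!is.finite(dt) || dt <= 0) stop("simulate: dt must be > 0")
  if (!is.finite(duration) || duration <= protocol_end(protocol))
    stop("simulate: duration must exceed the end of the stimulation (",
         format(protocol_end(protocol)), " s)")
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9)
    stop("simulate: duration must be an integer multiple of dt")
  edges <- c(burst_onsets(protocol), burst_onsets(protocol) + burst_duration(protocol))
  if (any(abs(edges / dt - round(edges / dt)) > 1e-6))
    stop("simulate: burst boundaries must fall on the dt grid ",
         "(choose dt so that onset and n_pulses/frequency_hz are multiples of it)")
  time <- (0:n) * dt
  mid <- (seq_len(n) - 0.5) * dt
  src <- params$DAP * protocol$current_ma * protocol$frequency_hz * params$L *
    stimulus_envelope(mid, protocol)
  out <- rk4_core(src, dt, as.numeric(init_state),
                  params$Vm, params$Km, params$kS, params$kE, params$kGamma,
                  params$k1ads, params$k2ads, params$k3ads)
  if (!isTRUE(out$ok))
    stop(sprintf("simulate: integration failure, state became non-finite at t = %g s",
                 out$bad_step * dt))
  new_conc_trace(time, out$S, out$E, out$G, dt)
}

#' Simulate the dopamine release / reuptake / electrode model
#'
#' Integrates the four-equation kinetic system with a classical fixed-step
#' 4th-order Runge-Kutta scheme from a zero initial state. The states are the
#' striatal dopamine concentration (release minus Michaelis-Menten reuptake),
#' the dopamine concentration measured at the carbon-fiber electrode
#' (first-order transfer from the striatum, loss away from the electrode,
#' return of desorbed dopamine), and the adsorbed dopamine on the electrode
#' surface. The burst envelope is piecewise constant; grid nodes are placed
#' exactly at burst boundaries.
#'
#' @param params a [kinetic_params()]
#' @param protocol a [stim_protocol()]; must end before `duration`
#' @param duration total simulated time, s (integer multiple of `dt`)
#' @param dt integration step, s (default 1e-3)
#' @return a `conc_trace` with components `time`, `DA_S`, `DA_E`, `Gamma_DA`
#'   (uM) and `dt`
#' @examples
#' tr <- simulate_trace(wt_params(), stim_protocol(), duration = 8)
#' max(tr$DA_E)
#' @export
simulate_trace <- function(params, protocol, duration = 12, dt = 1e-3) {
  simulate_from_state(params, protocol, duration, dt, init_state = c(0, 0, 0))
}

#' @export
print.conc_trace <- function(x, ...) {
  cat(sprintf("Concentration trace: %d nodes, dt = %g s, %g s total\n",
              length(x$time), x$dt, max(x$time)))
  cat(sprintf("  peak [DA]_S = %.4g uM, peak [DA]_E = %.4g uM\n",
              max(x$DA_S), max(x$DA_E)))
  invisible(x)
}

#' FSCV recording container
#'
#' A measured (or synthetic) dopamine time series on the acquisition grid,
#' with free-form metadata (genotype, sample rate, seed, ...).
#'
#' @param time sample times, s, strictly increasing
#' @param da measured dopamine, uM
#' @param metadata named list of acquisition metadata
#' @return an object of class `fscv_recording`
#' @export
fscv_recording <- function(time, da, metadata = list()) {
  if (length(time) != length(da))
    stop("fscv_recording: time and da must have equal length")
  if (any(!is.finite(time)) || any(!is.finite(da)))
    stop("fscv_recording: time and da must be finite")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("fscv_recording: time must be strictly increasing")
  structure(list(time = as.numeric(time), da = as.numeric(da),
                 metadata = metadata),
            class = "fscv_recording")
}

#' Sample the electrode observable onto an acquisition grid
#'
#' Downsamples the electrode-measured dopamine series of a simulated trace to
#' the FSCV acquisition rate by nearest-grid-node selection, producing a
#' recording of `floor(duration * sample_rate) + 1` samples starting at t = 0.
#'
#' @param trace a `conc_trace` from [simulate_trace()]
#' @param sample_rate acquisition rate, Hz; must not exceed `1/dt`
#' @return an [fscv_recording()]
#' @export
sample_recording <- function(trace, sample_rate) {
  stopifnot(inherits(trace, "conc_trace"))
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_recording: sample_rate must be > 0")
  if (sample_rate > 1 / trace$dt + 1e-9)
    stop("sample_recording: sample_rate exceeds the simulation resolution 1/dt")
  duration <- max(trace$time)
  m <- floor(duration * sample_rate + 1e-9)
  t_out <- (0:m) / sample_rate
  idx <- pmin(round(t_out / trace$dt) + 1L, length(trace$time))
  fscv_recording(t_out, trace$DA_E[idx],
                 metadata = list(sample_rate_hz = sample_rate))
}

#' @export
print.fscv_recording <- function(x, ...) {
  cat(sprintf("FSCV recording: %d samples over %g s\n",
              length(x$time), max(x$time) - min(x$time)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}
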