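# Shared fixtures: the standard burst protocol and a parameter set with all
# electrode/adsorption pathways switched off (pure release + reuptake).
std_protocol <- function(onset_s = 2, ...) stim_protocol(onset_s = onset_s, ...)

release_only_params <- function(Vm = 0, DAP = 0.67, ...) {
  kinetic_params(Vm = Vm, DAP = DAP, kS = 0, kE = 0, kGamma = 0,
                 k1ads = 0, k2ads = 0, k3ads = 0, ...)
}

# Noise-free synthetic recording for a parameter set under a protocol.
clean_recording <- function(params, protocol = std_protocol(), duration = 12,
                            sample_rate = 10) {
  sample_recording(simulate_trace(params, protocol, duration), sample_rate)
}
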