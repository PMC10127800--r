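# Independent fixed-step forward-Euler integrator of the three-state system,
# written in plain R against the model equations. Deliberately separate from
# the package's RK4 path so the two can be cross-checked.
euler_oracle <- function(params, protocol, duration, dt) {
  n <- round(duration / dt)
  mid <- (seq_len(n) - 0.5) * dt
  src <- params$DAP * protocol$current_ma * protocol$frequency_hz * params$L *
    stimulus_envelope(mid, protocol)
  S <- E <- G <- numeric(n + 1)
  s <- e <- g <- 0
  vm <- params$Vm; km <- params$Km; ks <- params$kS; ke <- params$kE
  kg <- params$kGamma; k1 <- params$k1ads; k2 <- params$k2ads; k3 <- params$k3ads
  for (i in seq_len(n)) {
    ds <- src[i] - vm * s / (s + km)
    de <- ks * s - ke * e + kg * g
    dg <- k1 * e - k2 * e * g - k3 * g
    s <- s + dt * ds; e <- e + dt * de; g <- g + dt * dg
    S[i + 1] <- s; E[i + 1] <- e; G[i + 1] <- g
  }
  list(time = (0:n) * dt, DA_S = S, DA_E = E, Gamma_DA = G)
}

# Two-sided permutation test on the difference of group means.
perm_test_p <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
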