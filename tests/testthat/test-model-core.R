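test_that("reuptake rate follows Michaelis-Menten kinetics", {
  p <- wt_params()  # Vm = 7.4, Km = 0.2
  expect_equal(reuptake_rate(p$Km, p), p$Vm / 2)      # half-saturation
  expect_equal(reuptake_rate(0, p), 0)                # no substrate
  expect_equal(reuptake_rate(100 * p$Km, p), 7.4 * 100 / 101)
  expect_error(reuptake_rate(-0.1, p), "da_s")
  # saturation and monotonicity on a broad concentration grid
  grid <- c(0, 10^seq(-3, 3, length.out = 50))
  v <- reuptake_rate(grid, p)
  expect_true(all(v <= p$Vm))
  expect_true(all(diff(v) >= 0))
})

test_that("with reuptake and electrode pathways off, the burst integrates to DAP*I*L*NP", {
  p <- release_only_params(Vm = 0, DAP = 0.67)
  prot <- std_protocol()  # 30 pulses, 50 Hz, 0.4 mA
  tr <- simulate_trace(p, prot, duration = 4)
  expected <- p$DAP * prot$current_ma * p$L * prot$n_pulses  # 8.04 uM
  expect_equal(expected, 8.04)
  expect_equal(max(tr$DA_S), expected, tolerance = 1e-3)
  # conservation: released dopamine stays in the striatal compartment
  expect_equal(tr$DA_S[length(tr$DA_S)], expected, tolerance = 1e-3)
  # and with L < 1 the plateau scales by the loss factor
  p2 <- release_only_params(Vm = 0, DAP = 0.67, L = 0.5)
  tr2 <- simulate_trace(p2, prot, duration = 4)
  expect_equal(max(tr2$DA_S), expected / 2, tolerance = 1e-3)
})

test_that("zero stimulation current yields identically zero trajectories", {
  prot <- stim_protocol(current_ma = 0)
  tr <- simulate_trace(wt_params(), prot, duration = 4)
  expect_true(all(tr$DA_S == 0))
  expect_true(all(tr$DA_E == 0))
  expect_true(all(tr$Gamma_DA == 0))
})

test_that("trajectories are nonnegative, bounded, and return toward zero", {
  prot <- std_protocol()
  for (p in list(wt_params(), ko_params())) {
    tr <- simulate_trace(p, prot, duration = 12)
    tol <- 1e-9
    expect_true(all(tr$DA_S >= -tol))
    expect_true(all(tr$DA_E >= -tol))
    expect_true(all(tr$Gamma_DA >= -tol))
    # total release bound
    expect_true(max(tr$DA_S) <=
                  p$DAP * prot$current_ma * p$L * prot$n_pulses)
    # decays back toward zero well after the stimulus
    expect_lt(tr$DA_E[length(tr$DA_E)], 0.05 * max(tr$DA_E))
  }
})

test_that("post-stimulus striatal decay is pointwise slower for smaller Vm", {
  prot <- std_protocol()
  tr_hi <- simulate_trace(wt_params(), prot, duration = 10)
  tr_lo <- simulate_trace(wt_params(Vm = 2.0), prot, duration = 10)
  after <- tr_hi$time > protocol_end(prot)
  expect_true(all(tr_lo$DA_S[after] >= tr_hi$DA_S[after] - 1e-12))
})

test_that("RK4 at dt = 1e-3 matches a fine-step Euler oracle on the observable", {
  prot <- std_protocol(onset_s = 1)
  for (p in list(wt_params(), ko_params())) {
    tr <- simulate_trace(p, prot, duration = 6, dt = 1e-3)
    orc <- euler_oracle(p, prot, duration = 6, dt = 1e-5)
    idx <- seq(1, length(orc$time), by = 100)  # oracle nodes on the RK4 grid
    expect_equal(orc$time[idx], tr$time)
    expect_lt(max(abs(tr$DA_E - orc$DA_E[idx])), 1e-3)
    expect_lt(max(abs(tr$DA_S - orc$DA_S[idx])), 1e-3)
  }
})

test_that("clamped electrode concentration drives adsorption to its closed-form steady state", {
  # with kS = kE = kGamma = 0 the electrode state stays at its initial value c,
  # and Gamma must converge to k1*c / (k2*c + k3)
  p <- kinetic_params(Vm = 0, DAP = 0, kS = 0, kE = 0, kGamma = 0,
                      k1ads = 0.1, k2ads = 0.05, k3ads = 0.1)
  c0 <- 2
  relax <- p$k2ads * c0 + p$k3ads
  dur <- ceiling(10 / relax) + 2
  tr <- fscvfit:::simulate_from_state(p, std_protocol(), duration = dur,
                                      dt = 1e-3, init_state = c(0, c0, 0))
  expect_true(all(abs(tr$DA_E - c0) < 1e-12))
  g_star <- p$k1ads * c0 / (p$k2ads * c0 + p$k3ads)
  expect_equal(tr$Gamma_DA[length(tr$Gamma_DA)], g_star, tolerance = 1e-3)
})

test_that("a diverging integration reports the first non-finite time point", {
  p <- wt_params(kGamma = 1e8, k1ads = 1e8)  # stiff beyond the fixed step
  expect_error(simulate_trace(p, std_protocol(), duration = 4),
               "integration failure.*t = ")
})

test_that("simulation preconditions are validated", {
  expect_error(simulate_trace(wt_params(), std_protocol(), duration = 2),
               "duration")
  expect_error(simulate_trace(wt_params(), std_protocol(), duration = 4, dt = -1),
               "dt")
  expect_error(
    simulate_trace(wt_params(), stim_protocol(onset_s = 1 / 3), duration = 4),
    "burst boundaries")
})

test_that("the observable is a nearest-node downsample of the electrode state", {
  tr <- simulate_trace(wt_params(), std_protocol(), duration = 10, dt = 1e-3)
  rec <- sample_recording(tr, 10)
  expect_length(rec$time, 101)  # floor(duration * rate) + 1
  expect_equal(rec$time, (0:100) / 10)
  expect_equal(rec$da, tr$DA_E[round(rec$time / tr$dt) + 1])
  # identity at the full simulation rate
  rec_full <- sample_recording(tr, 1 / tr$dt)
  expect_equal(rec_full$da, tr$DA_E)
  # a constant trace is invariant under downsampling
  n <- length(tr$time)
  flat <- fscvfit:::new_conc_trace(tr$time, rep(1, n), rep(0.7, n), rep(0, n),
                                   tr$dt)
  expect_true(all(sample_recording(flat, 25)$da == 0.7))
  expect_error(sample_recording(tr, 2000), "resolution|exceeds")
})
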