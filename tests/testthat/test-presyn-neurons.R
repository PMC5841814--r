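test_that("unstimulated neuron relaxes to the resting fixed point", {
  st <- neuron_state(V = -65)  # start off the fixed point
  for (i in 1:40000) st <- hh_step(st, Iapp = 0, I_inhib = 0, dt = 0.05)
  expect_lt(abs(st$V - (-70)), 0.5)
  r <- hh_rates(st$V)
  expect_lt(abs(st$m - r$alpha_m / (r$alpha_m + r$beta_m)), 1e-3)
  expect_lt(abs(st$h - r$alpha_h / (r$alpha_h + r$beta_h)), 1e-3)
  expect_lt(abs(st$n - r$alpha_n / (r$alpha_n + r$beta_n)), 1e-3)
  # a state at the fixed point stays there
  st2 <- hh_step(st, Iapp = 0, I_inhib = 0, dt = 0.05)
  expect_lt(abs(st2$V - st$V), 1e-4)
})

test_that("standard pulse train elicits exactly one spike per pulse", {
  tr <- cached_run(13, duration_ms = 5000, presyn_only = TRUE)
  s <- attr(tr, "summary")
  expect_equal(s$spikes_pre, 25)   # 5 Hz x 5 s
  expect_equal(s$spikes_int, 25)
})

test_that("non-finite neuron state raises an integration-failure error", {
  st <- neuron_state()
  st$V <- NaN
  expect_error(hh_step(st, 0, 0, 0.05), "integration failure")
})

test_that("GABA_A gate sigmoid has the documented midpoint structure", {
  # half activation exactly at V_Int = 100 (1 - CaCh)
  for (cach in c(0, 0.41, 0.59, 1)) {
    expect_equal(gaba_ginf(100 * (1 - cach), cach), 0.5)
  }
  # no morphine: midpoint at 0 mV, resting interneuron leaves the gate shut
  expect_lt(gaba_ginf(-70, 1), 1e-6)
  # partial block (CaCh = 0.59): rest still shut, spikes only graze the gate
  expect_lt(gaba_ginf(-70, 0.59), 1e-9)
  expect_equal(gaba_ginf(30, 0.59), 1 / (1 + exp(-(30 - 41) / 5)))
  # relaxation toward g_inf with tau 1 ms
  g <- gaba_gate_step(0, V_Int = 41, CaCh = 0.59, dt = 0.1)
  expect_equal(g, 0.1 * 0.5)
})

test_that("GABA_A current follows 10 g (V + 80)", {
  expect_equal(gaba_current(0.7, -80), 0)       # reversal potential
  expect_equal(gaba_current(1, -70), 100)
  expect_equal(gaba_current(0.25, -60), 50)
  expect_equal(gaba_current(0, 10), 0)
})

test_that("steady-state muOR activation is a bounded increasing Hill curve", {
  expect_equal(mor_steady(0), 0)
  expect_equal(mor_steady(0.1), 1)          # half of the maximum 2
  expect_lt(2 - mor_steady(1e6), 1e-4)      # asymptote
  doses <- c(0, 0.001, 0.01, 0.1, 1, 10, 100)
  m <- mor_steady(doses)
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= 0 & m <= 2))
  expect_error(mor_steady(-1), "non-negative")
})

test_that("without drug the willing-channel fraction returns to one", {
  st <- list(MOR = 0.5, CaCh = 0.3)
  for (i in 1:100000) st <- gpcr_step(st, Morph = 0, V_Int = 0, dt = 0.05)
  expect_gt(st$CaCh, 0.999)
  expect_lt(st$MOR, 0.01)   # five MOR time constants
})

test_that("MOR relaxes to its steady state with the 1 s time constant", {
  st <- list(MOR = 0, CaCh = 1)
  dt <- 0.05
  for (i in 1:(1000 / dt)) st <- gpcr_step(st, Morph = 0.1, V_Int = -70, dt = dt)
  # after one time constant: 1 - 1/e of the way to MOR_inf = 1
  expect_lt(abs(st$MOR - (1 - exp(-1))), 5e-3)
})

test_that("willing fraction at protocol steady state decreases with dose", {
  doses <- c(0, 0.01, 0.05, 0.1, 0.5, 1)
  dr <- dose_response_sweep(doses, duration_ms = 12000)
  expect_equal(dr$dose_uM, doses)
  expect_true(all(diff(dr$vgcc_pct) < 0))
  expect_true(all(dr$vgcc_pct >= 0 & dr$vgcc_pct <= 100))
  expect_equal(dr$ipsc_inhibition_pct[1], 0)          # self-reference
  expect_true(all(diff(dr$ipsc_inhibition_pct) > 0))  # monotone inhibition
})

test_that("halving dt changes the late-run willing fraction by < 1%", {
  cfg <- scenario_config(morphine_uM = 1)
  s1 <- attr(run_simulation(cfg, duration_ms = 12000, dt = 0.05,
                            presyn_only = TRUE), "summary")
  s2 <- attr(run_simulation(cfg, duration_ms = 12000, dt = 0.025,
                            presyn_only = TRUE), "summary")
  expect_lt(abs(s1$cach_late_mean - s2$cach_late_mean) / s2$cach_late_mean,
            0.01)
})

test_that("dose sweep rejects degenerate inputs", {
  expect_error(dose_response_sweep(numeric(0)), "empty")
  expect_error(dose_response_sweep(c(0, -0.1)), "non-negative")
})
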