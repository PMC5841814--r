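test_that("spontaneous-release rate has the printed half point and ceiling", {
  expect_equal(spontaneous_rate(50), 0.85 / 2)
  expect_lt(0.85 - spontaneous_rate(1e3), 1e-6)
  expect_lt(spontaneous_rate(0.1), 1e-4)
  cs <- seq(0, 100, by = 5)
  expect_true(all(diff(spontaneous_rate(cs)) > 0))
  expect_error(spontaneous_rate(-1))
})

test_that("NO boost is a bounded sigmoid of phosphorylated CaMKII", {
  expect_equal(no_boost(40), 0.005 / 2)   # midpoint: half of k_syt
  expect_lt(no_boost(0), 1e-7)            # e^16 denominator
  expect_lt(0.005 - no_boost(1e3), 1e-9)  # asymptote
  expect_error(no_boost(-1))
})

test_that("cleft glutamate follows production/clearance balance", {
  # pure decay at rate g_c * glt_factor
  g <- cleft_glut_step(10, E = 0, dt = 0.01, glt_factor = 1)
  expect_equal(g, 10 * (1 - 0.01 * 10))
  # steady state n_v g_v E / (g_c glt)
  g <- 0
  for (i in 1:5000) g <- cleft_glut_step(g, E = 0.2, dt = 0.01,
                                         glt_factor = 1)
  expect_lt(abs(g - 2 * 60 * 0.2 / 10), 1e-6)
  # halving the clearance doubles the steady state
  g2 <- 0
  for (i in 1:5000) g2 <- cleft_glut_step(g2, E = 0.2, dt = 0.01,
                                          glt_factor = 0.5)
  expect_lt(abs(g2 / g - 2), 1e-6)
  expect_error(cleft_glut_step(1, 0, glt_factor = 0))
})

test_that("vesicle pools conserve mass and respect the refractory rule", {
  vp <- vesicle_pool()
  # no release: R stays at the full-pool fixed point
  for (i in 1:1000) vp <- vesicle_pool_step(vp, 0, FALSE, t = i * 0.05)
  expect_equal(vp$R, 1, tolerance = 1e-12)
  expect_equal(vp$R + vp$E + vp$I, 1, tolerance = 1e-12)

  # double-vesicle release moves f_r R = R into E
  vp <- vesicle_pool_step(vesicle_pool(), n_ready = 2, t = 0)
  expect_lt(abs(vp$E - (1 - 0.05 / 3)), 1e-6)
  expect_equal(vp$R + vp$E + vp$I, 1, tolerance = 1e-12)

  # a second event 3 ms later is suppressed; 7 ms later it is allowed
  vp3 <- vesicle_pool_step(vp, n_ready = 1, t = 3)
  expect_equal(vp3$refractory_until, vp$refractory_until)
  vp7 <- vesicle_pool_step(vp, n_ready = 1, t = 7)
  expect_equal(vp7$refractory_until, 7 + 6.34)
  # conservation after arbitrary event sequences
  vp <- vesicle_pool()
  set.seed(11)
  t <- 0
  for (i in 1:2000) {
    t <- t + 0.05
    vp <- vesicle_pool_step(vp, sample(0:2, 1), sample(c(TRUE, FALSE), 1), t)
    expect_equal(vp$R + vp$E + vp$I, 1, tolerance = 1e-12)
  }
  expect_true(vp$R >= 0 && vp$E >= 0)
})

test_that("sensor chain is frozen at zero calcium", {
  occ <- sensor_ensemble(0, t_end = 5, n_rep = 200, seed = 7)
  expect_true(all(occ$X == 1))
  r <- ladder_rates(0)
  expect_equal(r$forward[1:5], rep(0, 5))
  expect_equal(r$forward[6], 30)  # isomerization is calcium independent
  expect_equal(r$backward, c(1:5 * 3, 8))
})

test_that("NO boost scales the association rate uniformly", {
  r0 <- ladder_rates(10, boost = 0)
  rb <- ladder_rates(10, boost = 0.005)
  expect_equal(rb$forward[1:5] / r0$forward[1:5], rep(1.005, 5))
  expect_equal(rb$backward, r0$backward)
})

test_that("stochastic sensor matches the mean-field oracle", {
  n_rep <- 4000
  for (ci in c(5, 10, 20)) {
    occ <- sensor_ensemble(ci, t_end = 2, n_rep = n_rep, seed = 42,
                           sample_every = 40)
    ora <- ladder_oracle(ci, t_end = 2, dt_fine = 0.002, sample_every = 1000)
    last <- nrow(occ)
    for (state in c("X", "X1", "X3", "X5", "X5s")) {
      p <- ora[[state]][nrow(ora)]
      se <- sqrt(max(p * (1 - p), 1e-6) / n_rep)
      expect_lt(abs(occ[[state]][last] - p), 3 * se + 0.01)
    }
  }
})

test_that("fast calcium settles at the pump/leak balance when channels shut", {
  cs <- presyn_calcium_state(c_fast = 2)
  for (i in 1:20000) cs <- fast_ca_step(cs, V_pre = -120, dt = 0.05)
  expect_lt(cs$m_Ca, 1e-5)          # Boltzmann gate closed far below V_mCa
  expect_lt(abs(cs$c_fast - 0.1), 0.01)  # returns to the rest balance point
})

test_that("PMCA pump runs at half maximum at its Hill constant", {
  p <- default_parameters()
  v <- p$values
  ci <- v[["k_pmca"]]
  pump <- v[["nu_pmca"]] * ci^2 / (ci^2 + v[["k_pmca"]]^2)
  expect_equal(pump, v[["nu_pmca"]] / 2)
})

test_that("IP3 relaxes to its basal level without gliotransmitter drive", {
  cs <- presyn_calcium_state(p = 0.4)
  for (i in 1:100000) cs <- slow_ca_step(cs, g_a = 0, dt = 0.05)
  # 5 s of relaxation at rate tau_p = 2e-4 / ms: one e-fold toward p0
  expect_lt(abs(cs$p - (0.16 + (0.4 - 0.16) * exp(-1))), 5e-3)
})

test_that("ER exchange relation couples c_slow and c_ER", {
  cs <- presyn_calcium_state(p = 1)   # strong IP3: store flux is active
  v <- default_parameters()$values
  c1 <- v[["c1"]]
  tot0 <- cs$c_ER + cs$c_slow / c1
  for (i in 1:20000) cs <- slow_ca_step(cs, g_a = 2, dt = 0.05)
  tot1 <- cs$c_ER + cs$c_slow / c1
  expect_lt(abs(tot1 - tot0), 1e-8)  # exchanged calcium is conserved
  expect_false(isTRUE(all.equal(cs$c_slow, 0)))  # and flux actually moved
})
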