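test_that("release gates relax to their calcium-dependent open fractions", {
  v <- default_parameters()$values
  # closed at zero calcium
  as <- astrocyte_state(c_a = 0, O1 = 0.5, O2 = 0.5, O3 = 0.5)
  for (i in 1:100000) as <- gates_step(as, dt = 0.05)
  expect_lt(astro_release_prob(as), 1e-6)
  # nearly open at high calcium (50 uM)
  as <- astrocyte_state(c_a = 50)
  for (i in 1:100000) as <- gates_step(as, dt = 0.01)
  expect_gt(astro_release_prob(as), 0.97)
  # quantitative steady state at the release threshold concentration
  ca <- 0.19669
  as <- astrocyte_state(c_a = ca)
  for (i in 1:200000) as <- gates_step(as, dt = 0.05)
  o1_inf <- v[["k1_plus"]] * ca / (v[["k1_plus"]] * ca + v[["k1_minus"]])
  expect_equal(as$O1, o1_inf, tolerance = 1e-4)
  expect_equal(o1_inf, 0.6484, tolerance = 1e-3)
})

test_that("no astrocytic release below the calcium threshold", {
  as <- astrocyte_state(c_a = 0.15, R_a = 0.6, E_a = 0.2,
                        O1 = 1, O2 = 1, O3 = 1)
  for (i in 1:100000) as <- astro_vesicle_step(as, dt = 0.05)
  expect_gt(as$R_a, 0.99)   # pool recovers fully: Theta = 0
  expect_lt(as$E_a, 1e-6)
  expect_equal(as$R_a + as$E_a + as$I_a, 1, tolerance = 1e-9)
  # Heaviside at exactly the threshold is zero (strict exceedance required)
  as2 <- astrocyte_state(c_a = 0.19669, R_a = 1, O1 = 1, O2 = 1, O3 = 1)
  as3 <- astro_vesicle_step(as2, dt = 0.05)
  expect_equal(as3$R_a, 1)
})

test_that("pool conservation holds during active release", {
  as <- astrocyte_state(c_a = 0.5, O1 = 0.7, O2 = 0.6, O3 = 0.8)
  for (i in 1:5000) {
    as <- astro_vesicle_step(as, dt = 0.05)
    expect_equal(as$R_a + as$E_a + as$I_a, 1, tolerance = 1e-9)
  }
  expect_gt(as$E_a, 0)
})

test_that("disabling gliotransmission pins release and transmitter to zero", {
  as <- astrocyte_state(c_a = 1, O1 = 1, O2 = 1, O3 = 1, g_a = 3,
                        glio_on = FALSE)
  for (i in 1:100) {
    as <- astro_vesicle_step(as, dt = 0.05)
    as <- gliotransmitter_step(as, dt = 0.05)
  }
  expect_equal(as$E_a, 0)
  expect_equal(as$g_a, 0)
})

test_that("gliotransmitter follows its production/clearance balance", {
  v <- default_parameters()$values
  # pure exponential decay at 10 / ms
  as <- astrocyte_state(g_a = 5)
  as <- gliotransmitter_step(as, dt = 0.01)
  expect_equal(as$g_a, 5 * (1 - 0.01 * 10))
  # constant E_a steady state
  as <- astrocyte_state(E_a = 0.1, R_a = 0.9)
  for (i in 1:3000) {
    as$E_a <- 0.1
    as <- gliotransmitter_step(as, dt = 0.01)
  }
  expected <- v[["n_v_a"]] * v[["g_v_a"]] * v[["kappa_a"]] * 0.1 /
    v[["g_c_a"]]
  expect_equal(as$g_a, expected, tolerance = 1e-6)
})

test_that("severing the mGluR pathway removes all agonist sensitivity", {
  glut_pulse <- run_fixture("glutamate_pulse_train")
  as_off <- astrocyte_state(mglur_on = FALSE)
  as_zero <- astrocyte_state(mglur_on = TRUE)
  for (g in glut_pulse$signal) {
    as_off <- astro_ca_step(as_off, glut = g, dt = 0.05)
    as_zero <- astro_ca_step(as_zero, glut = 0, dt = 0.05)
  }
  expect_equal(as_off$p_a, as_zero$p_a, tolerance = 1e-12)
  expect_equal(as_off$c_a, as_zero$c_a, tolerance = 1e-12)
  # while with the receptor on the same pulses do raise IP3
  as_on <- astrocyte_state(mglur_on = TRUE)
  for (g in glut_pulse$signal) as_on <- astro_ca_step(as_on, g, dt = 0.05)
  expect_gt(as_on$p_a, as_off$p_a)
})

test_that("glutamate drives astrocytic IP3 and calcium in the full engine", {
  tr <- cached_run(1, duration_ms = 15000)
  expect_gt(max(tr$c_astro_uM), 0.19669)   # threshold crossings occur
  expect_gt(max(tr$ip3_astro_uM), 0.2)
  expect_true(all(tr$h_a >= 0 & tr$h_a <= 1))
  expect_true(all(tr$pr_a >= 0 & tr$pr_a <= 1))
  expect_true(all(tr$Ra >= 0 & tr$Ea >= 0 & tr$Ra + tr$Ea <= 1 + 1e-9))
})
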