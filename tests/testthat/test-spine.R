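test_that("Mg unblock is monotone in voltage and relieved by morphine", {
  vs <- seq(-90, 40, by = 5)
  mg0 <- mg_block(0, vs)
  expect_true(all(diff(mg0) > 0))             # strictly increasing in V
  expect_gt(mg_block(0, 1000), 1 - 1e-6)      # fully unblocked at +inf
  expect_true(all(mg0 > 0 & mg0 < 1))
  for (dose in c(0.01, 0.1, 1, 10)) {
    expect_true(all(mg_block(dose, vs) >= mg0))   # relief at every voltage
  }
  # saturating effective K0 is the reported 4.8-fold of baseline
  v <- default_parameters()$values
  expect_equal((v[["k0_mg"]] + v[["mg_k_inc"]]) / v[["k0_mg"]], 4.8,
               tolerance = 1e-12)
  expect_error(mg_block(-1, 0))
})

test_that("AMPAR plasticity map has the exact algebraic endpoints", {
  ap0 <- ampa_plasticity(0)
  expect_equal(ap0$g_AMPA, 9 / 4)
  expect_equal(unlist(ap0[c("A", "AP1", "AP2", "AP1P2")]),
               rep(0.25, 4), ignore_attr = TRUE)
  ap_inf <- ampa_plasticity(1e6)
  expect_equal(ap_inf$g_AMPA, 54289 / 17424, tolerance = 1e-6)
  expect_equal(ap_inf$g_AMPA / ap0$g_AMPA, 54289 / 17424 / (9 / 4),
               tolerance = 1e-6)  # the ~1.386 saturating conductance ratio
  # pool normalization holds everywhere
  for (ph in c(0, 0.1, 0.5, 2, 10, 80)) {
    ap <- ampa_plasticity(ph)
    expect_equal(ap$A + ap$AP1 + ap$AP2 + ap$AP1P2, 1, tolerance = 1e-12)
  }
  expect_error(ampa_plasticity(-1))
})

test_that("CaMKII ladder conserves total kinase and drains at zero calcium", {
  ck <- camkii_state()
  total0 <- sum(ck$P)
  for (i in 1:4000) ck <- camkii_step(ck, c_post = 3, dt = 0.05)
  expect_equal(sum(ck$P), total0, tolerance = total0 * 1e-9)
  expect_gt(ph_camkii(ck), 0)
  expect_equal(ck$P[1] + ph_camkii(ck), total0, tolerance = 1e-9)

  # zero calcium: v1 = v2 = 0, mass drains back toward P0
  ck$e_p <- 0.1  # active phosphatase
  ph_before <- ph_camkii(ck)
  ph_path <- numeric(0)
  for (i in 1:4000) {
    ck <- camkii_step(ck, c_post = 0, dt = 0.05)
    if (i %% 500 == 0) ph_path <- c(ph_path, ph_camkii(ck))
  }
  expect_true(all(diff(c(ph_before, ph_path)) < 0))  # monotone decay
  expect_equal(sum(ck$P), total0, tolerance = total0 * 1e-9)
})

test_that("autophosphorylation rate hits its Hill midpoint at K_H1", {
  v <- default_parameters()$values
  cr4 <- (v[["K_H1"]] / v[["K_H1"]])^4
  expect_equal(v[["k1_cam"]] * cr4 / (1 + cr4), v[["k1_cam"]] / 2)
})

test_that("spine voltage is a passive first-order membrane", {
  sp <- spine_state(V_post = -50)
  for (i in 1:20000) sp <- spine_voltage_step(sp, I_syn = 0, dt = 0.05)
  expect_equal(sp$V_post, -70, tolerance = 1e-6)
  # constant drive: V* = V_rest + R_m I
  for (i in 1:20000) sp <- spine_voltage_step(sp, I_syn = 20, dt = 0.05)
  expect_equal(sp$V_post, -70 + 0.5 * 20, tolerance = 1e-6)
})

test_that("receptor currents vanish at their reversal potentials", {
  sp <- spine_state(V_post = 0, m_AMPA = 0.5, m_NMDA = 0.5)
  ap <- ampa_plasticity(0)
  expect_equal(ampa_step(sp, ap, glut = 10, g_a = 1)$I_AMPA, 0)
  expect_equal(nmda_step(sp, glut = 10, g_a = 1, Morph = 0)$I_NMDA, 0)
})

test_that("receptor gates decay without transmitter and saturate with it", {
  v <- default_parameters()$values
  sp <- spine_state(m_AMPA = 0.4, m_NMDA = 0.4)
  ap <- ampa_plasticity(0)
  sp2 <- ampa_step(sp, ap, glut = 0, g_a = 0, dt = 0.1)$state
  expect_equal(sp2$m_AMPA, 0.4 * (1 - 0.1 * v[["beta_ampa"]]))
  sp3 <- nmda_step(sp, glut = 0, g_a = 0, Morph = 0, dt = 0.1)$state
  expect_equal(sp3$m_NMDA, 0.4 * (1 - 0.1 * v[["beta_nmda"]]))
  # saturating drive fixed point alpha D / (alpha D + beta)
  sp4 <- spine_state()
  for (i in 1:40000) sp4 <- ampa_step(sp4, ap, glut = 50, g_a = 0)$state
  D <- v[["alpha_ampa"]] * v[["a1_ampa"]] * 50
  expect_equal(sp4$m_AMPA, D / (D + v[["beta_ampa"]]), tolerance = 1e-6)
})

test_that("morphine raises NMDAR conductance by at most 15% of baseline", {
  sp <- spine_state(V_post = -40, m_NMDA = 0.1)
  v <- default_parameters()$values
  i0 <- nmda_step(sp, glut = 0, g_a = 0, Morph = 0)$I_NMDA
  i_hi <- nmda_step(sp, glut = 0, g_a = 0, Morph = 1e6)$I_NMDA
  mg0 <- mg_block(0, -40); mg_hi <- mg_block(1e6, -40)
  # conductance part of the increase, with the Mg factor divided out
  expect_equal((i_hi / mg_hi) / (i0 / mg0), 1.15, tolerance = 1e-3)
  # postsynaptic muOR off: dose is ignored entirely
  sp_off <- spine_state(V_post = -40, m_NMDA = 0.1, mu_or_post_on = FALSE)
  expect_equal(nmda_step(sp_off, 0, 0, Morph = 1)$I_NMDA, i0)
})

test_that("voltage-dependent NMDAR conductance is zero at its anchor point", {
  v <- default_parameters()$values
  sp <- spine_state(V_post = v[["v0_gvd"]], g_VD = 0.2)
  for (i in 1:2000) sp <- nmda_step(sp, 0, 0, 0, dt = 0.05)$state
  expect_lt(sp$g_VD, 1e-6)
})

test_that("spine calcium returns to its 100 nM resting point", {
  sp <- spine_state(c_post = 2)
  for (i in 1:80000) sp <- post_ca_step(sp, I_AMPA = 0, I_NMDA = 0, B = 0)
  expect_equal(sp$c_post, 0.1, tolerance = 1e-4)
  # buffering factor vanishes at saturating calcium
  v <- default_parameters()$values
  theta <- function(c) v[["b_t"]] * v[["k_endo"]] / (v[["k_endo"]] + c)^2
  expect_lt(theta(1e5), 1e-3)
  expect_gt(theta(0.1), 19)
})
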