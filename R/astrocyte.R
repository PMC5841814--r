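#' Astrocyte state constructor
#'
#' @param c_a Cytosolic calcium (uM).
#' @param p_a IP3 (uM).
#' @param h_a IP3R inactivation gate in `[0, 1]`.
#' @param O1,O2,O3 Release-gate open probabilities.
#' @param R_a,E_a Vesicle pool fractions (`I_a = 1 - R_a - E_a`).
#' @param g_a Extrasynaptic gliotransmitter (uM).
#' @param mglur_on,glio_on Flags for the metabotropic receptor pathway and
#'   for gliotransmitter release.
#' @return An `astrocyte_state` list.
#' @export
astrocyte_state <- function(c_a = 0.07, p_a = 0.05, h_a = 0.8,
                            O1 = 0, O2 = 0, O3 = 0, R_a = 1, E_a = 0,
                            g_a = 0, mglur_on = TRUE, glio_on = TRUE) {
  structure(list(c_a = c_a, p_a = p_a, h_a = h_a, O1 = O1, O2 = O2, O3 = O3,
                 R_a = R_a, E_a = E_a, I_a = 1 - R_a - E_a, g_a = g_a,
                 mglur_on = mglur_on, glio_on = glio_on),
            class = "astrocyte_state")
}

#' Astrocytic IP3 / calcium update
#'
#' One Euler step of the astrocytic second-messenger system: IP3 is produced
#' by a glutamate-driven (mGluR/PLC-beta) term — severed entirely when
#' `mglur_on` is `FALSE` — and by calcium-modulated PLC-delta, and is removed
#' by IP3-3K (calcium dependent) and IP-5P; the IP3R inactivation gate `h_a`
#' follows Li-Rinzel kinetics; cytosolic calcium exchanges with the ER
#' through the IP3R channel flux (with the dynamic gate, `h_a^3`), the SERCA
#' pump and a leak.  ER calcium follows from conservation of the total free
#' calcium at fixed ER/cytosol volume ratio.
#'
#' @param as An [astrocyte_state()].
#' @param glut Cleft glutamate (uM), the mGluR agonist.
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `astrocyte_state`.
#' @export
astro_ca_step <- function(as, glut, dt = 0.05,
                          params = default_parameters()) {
  stopifnot(glut >= 0)
  v <- params$values
  hills <- function(x, K, n = 1) x^n / (x^n + K^n)
  ca <- as$c_a; pa <- as$p_a; ha <- as$h_a
  cER <- (v[["c_tot_a"]] - ca) / v[["c1a"]]
  m_inf <- hills(pa, v[["d1a"]])
  n_inf <- hills(ca, v[["d5a"]])
  j_chan <- v[["c1a"]] * v[["r_ca"]] * m_inf^3 * n_inf^3 * ha^3 * (ca - cER)
  j_pump <- v[["v_er"]] * ca^2 / (ca^2 + v[["K_er"]]^2)
  j_leak <- v[["c1a"]] * v[["r_l"]] * (ca - cER)
  K_eff <- v[["K_R"]] * (1 + (v[["K_p"]] / v[["K_R"]]) *
                           hills(ca, v[["K_pi"]]))
  agonist <- if (as$mglur_on && glut > 0)
    v[["nu_beta"]] * hills(glut, K_eff, 0.7) else 0
  plcd <- v[["nu_delta"]] / (1 + pa / v[["k_delta"]]) *
    hills(ca, v[["K_plcd"]], 2)
  degr <- v[["nu_3k"]] * hills(ca, v[["K_D"]], 4) * hills(pa, v[["K_3"]]) +
    v[["r_5"]] * pa
  a_ha <- v[["a2a"]] * v[["d2a"]] * (pa + v[["d1a"]]) / (pa + v[["d3a"]])
  b_ha <- v[["a2a"]] * ca
  as$c_a <- max(ca + dt * (-j_chan - j_pump - j_leak), 0)
  as$p_a <- max(pa + dt * (agonist + plcd - degr), 0)
  as$h_a <- ha + dt * (a_ha * (1 - ha) - b_ha * ha)
  as
}

#' Release-gate update
#'
#' The three independent calcium-binding gates that license astrocytic
#' vesicle fusion relax toward `O_j_inf = k_j_plus c / (k_j_plus c +
#' k_j_minus)`; the release-site open probability is their product
#' `Pr_a = O1 O2 O3`.
#'
#' @param as An [astrocyte_state()].
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `astrocyte_state`.
#' @export
gates_step <- function(as, dt = 0.05, params = default_parameters()) {
  stopifnot(as$c_a >= 0)
  v <- params$values
  ca <- as$c_a
  step1 <- function(O, kp, km) O + dt * (kp * ca - (kp * ca + km) * O)
  as$O1 <- step1(as$O1, v[["k1_plus"]], v[["k1_minus"]])
  as$O2 <- step1(as$O2, v[["k2_plus"]], v[["k2_minus"]])
  as$O3 <- step1(as$O3, v[["k3_plus"]], v[["k3_minus"]])
  as
}

#' Release-site open probability
#' @param as An [astrocyte_state()].
#' @return `O1 * O2 * O3`.
#' @export
astro_release_prob <- function(as) as$O1 * as$O2 * as$O3

#' Astrocytic vesicle pool update
#'
#' Release drive `Theta(c_a - c_thresh) Pr_a R_a` is active only while
#' cytosolic calcium strictly exceeds the 196.69 nM threshold
#' (`Theta(0) = 0`); pools recover with the 800 ms / 3 ms constants and
#' `R_a + E_a + I_a = 1` is preserved.  With gliotransmission disabled the
#' effective pool is pinned to zero.
#'
#' @param as An [astrocyte_state()].
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `astrocyte_state`.
#' @export
astro_vesicle_step <- function(as, dt = 0.05, params = default_parameters()) {
  v <- params$values
  rel <- if (as$c_a > v[["c_thresh"]]) astro_release_prob(as) * as$R_a else 0
  I_a <- 1 - as$R_a - as$E_a
  if (as$glio_on) {
    as$R_a <- as$R_a + dt * (I_a / v[["tau_rec_a"]] - rel)
    as$E_a <- as$E_a + dt * (-as$E_a / v[["tau_inact_a"]] + rel)
  } else {
    as$R_a <- as$R_a + dt * I_a / v[["tau_rec_a"]]
    as$E_a <- 0
  }
  as$I_a <- 1 - as$R_a - as$E_a
  as
}

#' Gliotransmitter concentration update
#'
#' `d g_a/dt = n_v_a g_v_a kappa_a E_a - g_c_a g_a`: production from the
#' 12-vesicle pool (20 mM vesicular content expressed in uM, scaled by the
#' documented vesicular-to-extrasynaptic volume ratio `kappa_a`) and
#' first-order clearance at 10 / ms.
#'
#' @param as An [astrocyte_state()].
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `astrocyte_state`.
#' @export
gliotransmitter_step <- function(as, dt = 0.05,
                                 params = default_parameters()) {
  v <- params$values
  if (as$glio_on) {
    as$g_a <- max(as$g_a + dt * (v[["n_v_a"]] * v[["g_v_a"]] *
                                   v[["kappa_a"]] * as$E_a -
                                   v[["g_c_a"]] * as$g_a), 0)
  } else {
    as$g_a <- 0
  }
  as
}
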