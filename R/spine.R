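#' Spine state constructor
#'
#' @param V_post Spine potential (mV).
#' @param m_AMPA,m_NMDA Receptor gating fractions.
#' @param g_VD Voltage-dependent NMDAR conductance component (nS).
#' @param c_post Spine calcium (uM).
#' @param mu_or_post_on Flag: postsynaptic mu-opioid receptors active.
#' @return A `spine_state` list.
#' @export
spine_state <- function(V_post = -70, m_AMPA = 0, m_NMDA = 0, g_VD = 0,
                        c_post = 0.1, mu_or_post_on = TRUE) {
  structure(list(V_post = V_post, m_AMPA = m_AMPA, m_NMDA = m_NMDA,
                 g_VD = g_VD, c_post = c_post,
                 mu_or_post_on = mu_or_post_on),
            class = "spine_state")
}

#' Passive spine voltage update
#'
#' `tau_post dV/dt = -(V - V_rest) + R_m I_syn` with
#' `I_syn = -(I_AMPA + I_NMDA)`; the spine is a passive membrane producing
#' EPSP-like deflections, no action potentials.
#'
#' @param sp A [spine_state()].
#' @param I_syn Synaptic current (pA, depolarizing positive).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `spine_state`.
#' @export
spine_voltage_step <- function(sp, I_syn, dt = 0.05,
                               params = default_parameters()) {
  v <- params$values
  stopifnot(v[["tau_post"]] > 0)
  sp$V_post <- sp$V_post + dt * (-(sp$V_post - v[["v_rest_post"]]) +
                                   v[["r_m"]] * I_syn) / v[["tau_post"]]
  sp
}

#' AMPA receptor update and current
#'
#' Gating is driven by `0.42 glut + 0.01 g_a` (weighted synaptic plus
#' astrocytic glutamate); the current uses the plasticity-mapped conductance:
#' `I_AMPA = s_ampa g_map m_AMPA (V - V_AMPA)`.
#'
#' @param sp A [spine_state()].
#' @param ap An [ampa_plasticity()] (for the current conductance).
#' @param glut Cleft glutamate (uM).
#' @param g_a Gliotransmitter (uM).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return List with the updated `spine_state` and the current `I_AMPA` (pA,
#'   computed at the pre-step voltage).
#' @export
ampa_step <- function(sp, ap, glut, g_a, dt = 0.05,
                      params = default_parameters()) {
  v <- params$values
  i_ampa <- v[["s_ampa"]] * ap$g_AMPA * sp$m_AMPA *
    (sp$V_post - v[["v_ampa"]])
  drive <- v[["a1_ampa"]] * glut + v[["a2_ampa"]] * g_a
  sp$m_AMPA <- sp$m_AMPA + dt * (v[["alpha_ampa"]] * drive *
                                   (1 - sp$m_AMPA) -
                                   v[["beta_ampa"]] * sp$m_AMPA)
  list(state = sp, I_AMPA = i_ampa)
}

#' Magnesium unblock fraction of the NMDA receptor
#'
#' Voltage- and dose-dependent relief of the Mg2+ pore block:
#' `Mg = 1 / (1 + [Mg]0 (k0 + 15.58 H)^{-1} exp(-z (delta + 0.11 H) F V / RT))`
#' where `H = 1/(1 + (0.1/Morph)^1.2)` is the receptor occupancy Hill term
#' (0 with no drug).  Morphine raises the dissociation constant (4.8-fold at
#' saturation) and the electrical distance of the binding site, relieving the
#' block at depolarized potentials.  When the postsynaptic mu-opioid
#' receptors are off the dose is forced to zero.
#'
#' @param Morph Dose (uM).
#' @param V_post Spine potential (mV).
#' @param params Model parameters.
#' @return Unblocked fraction in `(0, 1)`.
#' @export
mg_block <- function(Morph, V_post, params = default_parameters()) {
  stopifnot(all(Morph >= 0))
  v <- params$values
  H <- ifelse(Morph == 0, 0, 1 / (1 + (v[["mor_kd"]] / Morph)^v[["mor_hill"]]))
  K0 <- v[["k0_mg"]] + v[["mg_k_inc"]] * H
  delta <- v[["delta_mg"]] + v[["delta_mg_inc"]] * H
  1 / (1 + (v[["mg0"]] / K0) *
         exp(-v[["z_mg"]] * delta * v[["f_rt"]] * V_post))
}

#' NMDA receptor update and current
#'
#' Gating is driven by `k1 glut + k2 g_a`; the conductance is the sum of a
#' voltage-independent part with its saturable morphine increment (up to
#' +0.15 nS, i.e. +15% of the 1 nS baseline), and the voltage-dependent part
#' `g_VD` relaxing toward `k (V - V0)` (clipped at zero).  The current
#' carries the Mg2+ unblock factor.
#'
#' @param sp A [spine_state()].
#' @param glut,g_a Synaptic and astrocytic glutamate (uM).
#' @param Morph Dose (uM); ignored (treated as 0) when `sp$mu_or_post_on` is
#'   `FALSE`.
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return List with updated `spine_state` and current `I_NMDA` (pA).
#' @export
nmda_step <- function(sp, glut, g_a, Morph, dt = 0.05,
                      params = default_parameters()) {
  v <- params$values
  morph_eff <- if (sp$mu_or_post_on) Morph else 0
  H <- if (morph_eff == 0) 0 else
    1 / (1 + (v[["mor_kd"]] / morph_eff)^v[["mor_hill"]])
  g_nmda <- v[["g_vi"]] + v[["g_nmda_morph_inc"]] * H + sp$g_VD
  mg <- mg_block(morph_eff, sp$V_post, params)
  i_nmda <- g_nmda * sp$m_NMDA * mg * (sp$V_post - v[["v_nmda"]])
  drive <- v[["k1_nmda"]] * glut + v[["k2_nmda"]] * g_a
  sp$m_NMDA <- sp$m_NMDA + dt * (v[["alpha_nmda"]] * drive *
                                   (1 - sp$m_NMDA) -
                                   v[["beta_nmda"]] * sp$m_NMDA)
  gvd_inf <- max(v[["k_gvd"]] * (sp$V_post - v[["v0_gvd"]]), 0)
  sp$g_VD <- sp$g_VD + dt * (gvd_inf - sp$g_VD) / v[["tau_gvd"]]
  list(state = sp, I_NMDA = i_nmda)
}

#' Spine calcium update
#'
#' Calcium influx through AMPAR (weight 0.012), NMDAR (weight 0.06) and the
#' stochastic L-type channels (`I_L = g_L B(N, P_open) (V - V_L)`, with `B`
#' a binomial draw of open channels), an extrusion pump
#' `k_s (c - c_rest)`, and fast endogenous buffering through the factor
#' `theta = b_t K_endo / (K_endo + c)^2` dividing the whole right-hand side.
#'
#' @param sp A [spine_state()].
#' @param I_AMPA,I_NMDA Receptor currents (pA).
#' @param dt Time step (ms).
#' @param B Number of open L-type channels; when `NULL` it is drawn as
#'   `rbinom(1, n_chan, p_open)` from R's RNG.
#' @param params Model parameters.
#' @return Updated `spine_state`.
#' @export
post_ca_step <- function(sp, I_AMPA, I_NMDA, dt = 0.05, B = NULL,
                         params = default_parameters()) {
  v <- params$values
  if (is.null(B)) B <- stats::rbinom(1, v[["n_chan"]], v[["p_open"]])
  i_l <- v[["g_l_ca"]] * B * (sp$V_post - v[["v_l_ca"]])
  theta <- v[["b_t"]] * v[["k_endo"]] / (v[["k_endo"]] + sp$c_post)^2
  influx <- -(v[["eta"]] * I_AMPA + v[["gamma_nmda"]] * I_NMDA + i_l) *
    v[["ca_conv_spine"]]
  spump <- v[["k_s"]] * (sp$c_post - v[["c_post_rest"]])
  sp$c_post <- max(sp$c_post + dt * (influx - spump) / (1 + theta), 0)
  sp
}

#' CaMKII state constructor
#'
#' @param P Numeric vector of length 11: concentrations of the 0..10-fold
#'   phosphorylated kinase (uM); defaults to all mass unphosphorylated at
#'   the 80 uM total.
#' @param e_p Free PP1 (uM).
#' @param I_free Free phosphorylated inhibitor-1 (uM).
#' @param params Model parameters.
#' @return A `camkii_state` list.
#' @export
camkii_state <- function(P = NULL, e_p = NULL, I_free = 0,
                         params = default_parameters()) {
  v <- params$values
  if (is.null(P)) P <- c(v[["camkii_total"]], rep(0, 10))
  stopifnot(length(P) == 11)
  if (is.null(e_p)) e_p <- v[["ep0"]]
  structure(list(P = P, e_p = e_p, I_free = I_free), class = "camkii_state")
}

#' CaMKII phosphorylation ladder update
#'
#' Advances the 11-state phosphorylation ladder (calcium-dependent initiation
#' `v1`, autophosphorylation `v2` with the ring coefficient pattern 1, 1.8,
#' 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1, and PP1-mediated dephosphorylation
#' `i v3`) together with the PP1 / phosphorylated-inhibitor-1 pool (PKA
#' phosphorylation of I1, calcineurin dephosphorylation with a cubic calcium
#' Hill term, and PP1-I1P binding).  Total kinase is conserved by
#' construction.
#'
#' @param ck A [camkii_state()].
#' @param c_post Spine calcium (uM).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `camkii_state`.
#' @export
camkii_step <- function(ck, c_post, dt = 0.05,
                        params = default_parameters()) {
  stopifnot(c_post >= 0)
  v <- params$values
  P <- ck$P
  cr4 <- (c_post / v[["K_H1"]])^4
  v1 <- 10 * v[["k1_cam"]] * cr4^2 * P[1] / (1 + cr4)^2
  v2 <- v[["k1_cam"]] * cr4 / (1 + cr4)
  sum_iP <- sum((1:10) * P[2:11])
  v3 <- v[["k2_cam"]] * ck$e_p / (v[["K_M"]] + sum_iP)
  coef <- c(1, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1)
  dP <- numeric(11)
  dP[1] <- -v1 + v3 * P[2]
  dP[2] <- v1 - v3 * P[2] - v2 * P[2] + 2 * v3 * P[3]
  for (i in 3:10) {
    # dP_i for i-fold phosphorylation, R index i+1
    dP[i] <- coef[i - 2] * v2 * P[i - 1] - (i - 1) * v3 * P[i] -
      coef[i - 1] * v2 * P[i] + i * v3 * P[i + 1]
  }
  dP[11] <- coef[9] * v2 * P[10] - 10 * v3 * P[11]
  P <- pmax(P + dt * dP, 0)
  hr3 <- (c_post / v[["K_H2"]])^3
  bind <- -v[["k3_cam"]] * ck$I_free * ck$e_p +
    v[["k4_cam"]] * (v[["ep0"]] - ck$e_p)
  e_p <- min(max(ck$e_p + dt * bind, 0), v[["ep0"]])
  I_free <- max(ck$I_free + dt * (bind + v[["nu_pka"]] * v[["i0"]] -
                                    v[["nu_can"]] * hr3 / (1 + hr3) *
                                    ck$I_free), 0)
  camkii_state(P = P, e_p = e_p, I_free = I_free, params = params)
}

#' Summed phosphorylated CaMKII
#'
#' `Ph.CaMKII = P1 + ... + P10` (the unphosphorylated pool P0 excluded);
#' `P0 + Ph.CaMKII` equals the conserved total.
#'
#' @param ck A [camkii_state()].
#' @return Concentration (uM).
#' @export
ph_camkii <- function(ck) sum(ck$P[2:11])

#' AMPA receptor plasticity map
#'
#' Kinase/phosphatase activities are saturable functions of phosphorylated
#' CaMKII (`EP = 1 + 30 ph^2/(1 + ph^2)`, `EK = 1 + 100 ph^2/(8^2 + ph^2)`);
#' the four phosphorylation pools of the receptor follow in closed form and
#' the conductance readout is `g = A + 2 (AP1 + AP2) + 4 AP1P2`, which
#' reduces to `A_T ((EP + 2 EK)/(EP + EK))^2`.  The map runs from
#' `9/4 A_T` at zero phosphorylation to `54289/17424 A_T` at saturation
#' (a ~39% ceiling; the pathological working point reaches about +30%).
#'
#' @param ph Phosphorylated CaMKII (uM).
#' @param params Model parameters.
#' @return An `ampa_plasticity` list with the pools `A`, `AP1`, `AP2`,
#'   `AP1P2` and the conductance `g_AMPA` (map units).
#' @export
ampa_plasticity <- function(ph = 0, params = default_parameters()) {
  stopifnot(all(ph >= 0))
  v <- params$values
  EP <- 1 + v[["ep_max"]] * ph^2 / (v[["ep_K"]]^2 + ph^2)
  EK <- 1 + v[["ek_max"]] * ph^2 / (v[["ek_K"]]^2 + ph^2)
  A_T <- v[["a_t"]]
  D <- (EK + EP)^2
  structure(list(
    A = A_T * EP * EP / D,
    AP1 = A_T * EK * EP / D,
    AP2 = A_T * EP * EK / D,
    AP1P2 = A_T * EK * EK / D,
    g_AMPA = A_T * ((EP + 2 * EK) / (EP + EK))^2
  ), class = "ampa_plasticity")
}

#' @rdname ampa_plasticity
#' @param ap An existing `ampa_plasticity` object (ignored; the map is
#'   memoryless and recomputed from `ph`).
#' @export
ampa_plasticity_update <- function(ap, ph, params = default_parameters()) {
  ampa_plasticity(ph = ph, params = params)
}
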