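#' Spontaneous release rate
#'
#' Sigmoidal rate of spontaneous single-vesicle fusion as a function of the
#' calcium concentration at the release site:
#' `lambda(c) = a3 / (1 + exp((a1 - c)/a2))` with a1 = 50 uM (half-maximum
#' point), a2 = 5 uM (slope) and a3 = 0.85 / ms (ceiling).  In the full model
#' a spontaneous event is drawn as a Poisson process with probability
#' `lambda dt` per step, gated to non-depolarized membrane.
#'
#' @param c_i Calcium concentration at the release site (uM).
#' @param params Model parameters.
#' @return Rate in 1/ms.
#' @export
spontaneous_rate <- function(c_i, params = default_parameters()) {
  stopifnot(all(c_i >= 0))
  v <- params$values
  v[["spont_a3"]] / (1 + exp((v[["spont_a1"]] - c_i) / v[["spont_a2"]]))
}

#' Nitric-oxide boost of sensor calcium affinity
#'
#' Retrograde feedback: once summed phosphorylated CaMKII crosses its
#' half-point (40 uM), the calcium association rate of the release sensor is
#' increased by up to `k_syt` (0.5%).  Returns the fractional increment, so
#' the effective association rate is `alpha * (1 + no_boost(sum_P))`.
#'
#' @param sum_P Summed phosphorylated CaMKII, `P1 + ... + P10` (uM).
#' @param params Model parameters.
#' @return Dimensionless increment in `[0, k_syt]`.
#' @export
no_boost <- function(sum_P, params = default_parameters()) {
  stopifnot(all(sum_P >= 0))
  v <- params$values
  v[["k_syt"]] / (1 + exp(-(sum_P - v[["p_half"]]) * v[["k_half"]]))
}

#' Cleft glutamate update
#'
#' `d glut/dt = n_v g_v E - g_c glt_factor glut`: production proportional to
#' the effective vesicle fraction (2 docked vesicles at 60 uM each),
#' first-order clearance by the astrocytic glutamate transporters.
#' `glt_factor` scales the clearance rate (1 = normal, 0.5 under morphine,
#' 1.5 when the transporters are stimulated).
#'
#' @param glut Cleft glutamate (uM).
#' @param E Effective vesicle fraction.
#' @param dt Time step (ms).
#' @param glt_factor Clearance scaling, must be positive.
#' @param params Model parameters.
#' @return Updated glutamate concentration (uM).
#' @export
cleft_glut_step <- function(glut, E, dt = 0.05, glt_factor = 1,
                            params = default_parameters()) {
  stopifnot(glt_factor > 0)
  v <- params$values
  g <- glut + dt * (v[["n_v"]] * v[["g_v"]] * E -
                      v[["g_c"]] * glt_factor * glut)
  max(g, 0)
}

#' Vesicle pool state constructor
#'
#' @param R,E Ready and effective fractions (`I = 1 - R - E`).
#' @param refractory_until Time (ms) before which release is forbidden.
#' @return A `vesicle_pool` list.
#' @export
vesicle_pool <- function(R = 1, E = 0, refractory_until = -Inf) {
  structure(list(R = R, E = E, I = 1 - R - E,
                 refractory_until = refractory_until),
            class = "vesicle_pool")
}

#' Vesicle pool update with release events
#'
#' Continuous recovery/inactivation (`dR/dt = I/tau_rec`,
#' `dE/dt = -E/tau_inac`) plus a discrete ready-to-effective transfer of
#' `f_r R` when a release fires: `f_r = n_ready/2` for evoked release (two
#' docked vesicles) or 0.5 for a spontaneous single-vesicle event.  Any event
#' (attempted or realized) within 6.34 ms of the previous one is suppressed
#' by the refractory rule.  `R + E + I = 1` is preserved exactly.
#'
#' @param vp A [vesicle_pool()].
#' @param n_ready Number of sensors in the releasable isomer state (0, 1, 2).
#' @param spont_event Logical; spontaneous single-vesicle event this step.
#' @param t Current time (ms).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated `vesicle_pool`.
#' @export
vesicle_pool_step <- function(vp, n_ready = 0, spont_event = FALSE, t = 0,
                              dt = 0.05, params = default_parameters()) {
  stopifnot(n_ready %in% 0:2)
  v <- params$values
  R <- vp$R; E <- vp$E
  refr <- vp$refractory_until
  f_r <- if (n_ready > 0) n_ready / 2 else if (spont_event) 0.5 else 0
  if (f_r > 0 && t >= refr) {
    moved <- f_r * R
    R <- R - moved
    E <- E + moved
    refr <- t + v[["t_refractory"]]
  }
  I <- 1 - R - E
  R <- R + dt * I / v[["tau_rec"]]
  E <- E + dt * (-E / v[["tau_inac"]])
  vesicle_pool(R = R, E = E, refractory_until = refr)
}

#' Sensor ladder transition rates
#'
#' Rates of the five-site calcium-sensor chain
#' `X <-> X1 <-> ... <-> X5 <-> X5*`: forward binding at
#' `(5 - k) alpha_eff c`, unbinding at `k beta`, and the calcium-independent
#' isomerization `gamma`/`delta` between `X5` and the releasable isomer.
#' `alpha_eff = alpha (1 + boost)` carries the NO feedback.
#'
#' @param c_i Calcium (uM).
#' @param boost NO increment from [no_boost()].
#' @param params Model parameters.
#' @return List with vectors `forward` (6 rates: X->X1 ... X5->X5*) and
#'   `backward` (6 rates: X1->X ... X5*->X5), all in 1/ms.
#' @export
ladder_rates <- function(c_i, boost = 0, params = default_parameters()) {
  stopifnot(c_i >= 0, boost >= 0)
  v <- params$values
  a_eff <- v[["sensor_alpha"]] * (1 + boost)
  list(
    forward = c((5:1) * a_eff * c_i, v[["sensor_gamma"]]),
    backward = c((1:5) * v[["sensor_beta"]], v[["sensor_delta"]])
  )
}

#' Stochastic sensor ensemble (CTMC)
#'
#' Simulates `n_rep` independent sensor chains at fixed calcium with exact
#' Gillespie transitions inside each Euler step (rates frozen at step start,
#' the same scheme the full engine uses) and returns mean state occupancies
#' over time.  Used to validate the stochastic sensor against the
#' deterministic mean-field oracle in [ladder_oracle()].
#'
#' @param c_i Calcium (uM).
#' @param t_end End time (ms).
#' @param dt Step (ms).
#' @param n_rep Number of replicate chains.
#' @param seed RNG seed.
#' @param sample_every Store occupancies every this many steps.
#' @param boost NO increment.
#' @param params Model parameters.
#' @return Data frame with `t_ms` and mean occupancies `X`, `X1` .. `X5`,
#'   `X5s`.
#' @export
sensor_ensemble <- function(c_i, t_end, dt = 0.05, n_rep = 2000, seed = 1,
                            sample_every = 10, boost = 0,
                            params = default_parameters()) {
  v <- params$values
  occ <- .ladder_ctmc_cpp(c_i, v[["sensor_alpha"]] * (1 + boost),
                          v[["sensor_beta"]], v[["sensor_gamma"]],
                          v[["sensor_delta"]], t_end, dt, n_rep,
                          sample_every, seed)
  out <- as.data.frame(occ)
  names(out) <- c("t_ms", "X", paste0("X", 1:5), "X5s")
  out
}

#' Presynaptic calcium state constructor
#'
#' @param c_fast AP-driven (microdomain) calcium (uM).
#' @param c_slow Store-driven bulk calcium component (uM).
#' @param c_ER ER calcium (uM); defaults to the store total implied by
#'   `c0_pre`.
#' @param p IP3 (uM).
#' @param q Fraction of non-inactivated IP3 receptors.
#' @param m_Ca N-type channel gate fraction.
#' @param params Model parameters.
#' @return A `presyn_calcium_state` list.
#' @export
presyn_calcium_state <- function(c_fast = NULL, c_slow = 0, c_ER = NULL,
                                 p = NULL, q = 0.8, m_Ca = 0,
                                 params = default_parameters()) {
  v <- params$values
  if (is.null(c_fast)) c_fast <- v[["c_rest"]]
  if (is.null(c_ER)) c_ER <- (v[["c0_pre"]] - v[["c_rest"]]) / v[["c1"]]
  if (is.null(p)) p <- v[["p0"]]
  structure(list(c_fast = c_fast, c_slow = c_slow, c_ER = c_ER, p = p,
                 q = q, m_Ca = m_Ca), class = "presyn_calcium_state")
}

#' Fast (action-potential driven) presynaptic calcium step
#'
#' Updates the N-type channel gate (first-order relaxation to its Boltzmann
#' steady state) and the microdomain calcium from the two-gate channel
#' current, the PMCA pump (Hill n = 2 on total calcium) and the membrane
#' leak.  The calcium reversal potential is the Nernst value at the resting
#' intracellular concentration.
#'
#' @param cs A [presyn_calcium_state()].
#' @param V_pre Bouton membrane potential (mV).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated state.
#' @export
fast_ca_step <- function(cs, V_pre, dt = 0.05,
                         params = default_parameters()) {
  v <- params$values
  if (v[["c_ext"]] <= 0) stop("extracellular calcium must be positive")
  ci <- cs$c_fast + cs$c_slow
  v_ca <- v[["rt_zf"]] * log(v[["c_ext"]] / v[["c_rest"]])
  m_inf <- 1 / (1 + exp((v[["v_mca"]] - V_pre) / v[["k_mca"]]))
  i_ca <- v[["rho_ca"]] * v[["a_btn"]] * cs$m_Ca^2 * v[["g_ca_single"]] *
    (V_pre - v_ca) * 1e-3                      # pS * mV -> pA
  j_pmca <- v[["nu_pmca"]] * ci^2 / (ci^2 + v[["k_pmca"]]^2)
  j_leak <- v[["nu_leak"]] * (v[["c_ext"]] - ci)
  cs$m_Ca <- cs$m_Ca + dt * (m_inf - cs$m_Ca) / v[["tau_mca"]]
  cs$c_fast <- max(cs$c_fast +
                     dt * (-i_ca * v[["ca_conv_btn"]] + j_leak - j_pmca), 0)
  cs
}

#' Slow (store-driven) presynaptic calcium step
#'
#' Gliotransmitter binding to the presynaptic metabotropic receptors drives
#' IP3 production (Hill exponent 0.7) against a first-order return to the
#' basal level; the IP3 receptor gate q follows its opening/closing rates;
#' the slow calcium component exchanges with the ER through the channel
#' flux, SERCA pump and leak, with the ER balance
#' `d c_ER/dt = -(1/c1) d c_slow/dt`.  The store subsystem is gated by the
#' bulk calcium `c_rest + c_slow` (the ER does not see the brief AP
#' microdomain transient that drives the release sensor).
#'
#' @param cs A [presyn_calcium_state()].
#' @param g_a Extrasynaptic gliotransmitter (uM).
#' @param dt Time step (ms).
#' @param params Model parameters.
#' @return Updated state.
#' @export
slow_ca_step <- function(cs, g_a, dt = 0.05, params = default_parameters()) {
  v <- params$values
  cb <- max(v[["c_rest"]] + cs$c_slow, 0)
  m_inf <- cs$p / (cs$p + v[["d1"]])
  n_inf <- cb / (cb + v[["d5"]])
  j_chan <- v[["c1"]] * v[["nu1"]] * m_inf^3 * n_inf^3 * cs$q^3 *
    (cb - cs$c_ER)
  j_erpump <- v[["nu3"]] * cb^2 / (v[["k3"]]^2 + cb^2)
  j_erleak <- v[["c1"]] * v[["nu2"]] * (cb - cs$c_ER)
  dslow <- -j_chan - j_erpump - j_erleak
  a_q <- v[["a2"]] * v[["d2"]] * (cs$p + v[["d1"]]) / (cs$p + v[["d3"]])
  b_q <- v[["a2"]] * cb
  drive <- if (g_a > 0)
    v[["nu_g"]] * g_a^0.7 / (v[["k_g"]]^0.7 + g_a^0.7) else 0
  cs$c_slow <- cs$c_slow + dt * dslow
  cs$c_ER <- cs$c_ER + dt * (-dslow / v[["c1"]])
  cs$q <- cs$q + dt * (a_q * (1 - cs$q) - b_q * cs$q)
  cs$p <- cs$p + dt * (drive - v[["tau_p"]] * (cs$p - v[["p0"]]))
  cs
}
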