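#' Hodgkin-Huxley rate functions
#'
#' Voltage-dependent opening/closing rates of the sodium activation (m),
#' sodium inactivation (h) and potassium activation (n) gates, with the
#' conventions used by both presynaptic neurons (resting potential near
#' -70 mV).  The removable singularities of the alpha_n / alpha_m terms are
#' evaluated by their limits.
#'
#' @param V Membrane potential (mV).
#' @return A named list with elements `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n` (all in 1/ms).
#' @export
hh_rates <- function(V) {
  vtrap <- function(x, y) {
    ifelse(abs(x / y) < 1e-6, y * (1 - x / (2 * y)), x / (exp(x / y) - 1))
  }
  list(
    alpha_n = 0.01 * vtrap(-V - 60, 10),
    alpha_m = 0.1 * vtrap(-V - 45, 10),
    alpha_h = 0.07 * exp((-V - 70) / 20),
    beta_n = 0.125 * exp((-V - 70) / 80),
    beta_m = 4 * exp((-V - 70) / 18),
    beta_h = 1 / (exp((-V - 40) / 10) + 1)
  )
}

#' Construct a neuron state
#'
#' @param V Membrane potential (mV).
#' @param m,h,n Gating fractions in `[0, 1]`; default to their steady values
#'   `alpha/(alpha+beta)` at `V`.
#' @return A `neuron_state` list.
#' @export
neuron_state <- function(V = -70, m = NULL, h = NULL, n = NULL) {
  r <- hh_rates(V)
  if (is.null(m)) m <- r$alpha_m / (r$alpha_m + r$beta_m)
  if (is.null(h)) h <- r$alpha_h / (r$alpha_h + r$beta_h)
  if (is.null(n)) n <- r$alpha_n / (r$alpha_n + r$beta_n)
  structure(list(V = V, m = m, h = h, n = n), class = "neuron_state")
}

#' One forward-Euler Hodgkin-Huxley step
#'
#' Advances membrane potential and gating variables of a single-compartment
#' neuron by `dt` under an applied current density and an inhibitory
#' (GABA_A) current density.  Conductances are gNa = 120, gK = 36,
#' gL = 0.3 mS/cm2 with reversals +45, -82, -59.4 mV; membrane capacitance is
#' 1 uF/cm2 (absorbed, the standard convention).
#'
#' @param state A `neuron_state`.
#' @param Iapp Applied current density (uA/cm2).
#' @param I_inhib Inhibitory current density (uA/cm2); 0 for the interneuron.
#' @param dt Time step (ms), must be positive.
#' @return The updated `neuron_state`.
#' @export
hh_step <- function(state, Iapp, I_inhib = 0, dt = 0.05) {
  stopifnot(dt > 0)
  V <- state$V
  if (!all(is.finite(c(V, state$m, state$h, state$n))))
    stop("integration failure: non-finite neuron state (V = ", V, ")")
  r <- hh_rates(V)
  dV <- Iapp - 36 * state$n^4 * (V + 82) - 120 * state$m^3 * state$h *
    (V - 45) - 0.3 * (V + 59.4) - I_inhib
  neuron_state(
    V = V + dt * dV,
    m = state$m + dt * (r$alpha_m * (1 - state$m) - r$beta_m * state$m),
    h = state$h + dt * (r$alpha_h * (1 - state$h) - r$beta_h * state$h),
    n = state$n + dt * (r$alpha_n * (1 - state$n) - r$beta_n * state$n)
  )
}

#' GABA_A receptor gate update
#'
#' The activated receptor fraction relaxes with a 1 ms time constant toward a
#' sigmoid of the interneuron potential whose half-activation voltage is
#' shifted by the fraction of voltage-gated calcium channels remaining in the
#' willing state: `g_inf = 1 / (1 + exp(-(V_Int - 100 (1 - CaCh)) / 5))`.
#' When all channels are willing (`CaCh = 1`, no morphine) the midpoint sits
#' at 0 mV, so only interneuron spikes recruit the gate.
#'
#' @param g_frac Activated receptor fraction.
#' @param V_Int Interneuron membrane potential (mV).
#' @param CaCh Willing-state VGCC fraction in `[0, 1]`.
#' @param dt Time step (ms).
#' @param tau_g Gate time constant (ms).
#' @return Updated `g_frac`.
#' @export
gaba_gate_step <- function(g_frac, V_Int, CaCh, dt = 0.05, tau_g = 1) {
  stopifnot(CaCh >= 0, CaCh <= 1)
  g_frac + dt * (gaba_ginf(V_Int, CaCh) - g_frac) / tau_g
}

#' @rdname gaba_gate_step
#' @export
gaba_ginf <- function(V_Int, CaCh) {
  1 / (1 + exp(-(V_Int - 100 * (1 - CaCh)) / 5))
}

#' GABA_A current density on the pyramidal neuron
#'
#' `I_GABAA = 10 g (V_pre + 80)` in uA/cm2; the current vanishes at the
#' chloride reversal potential of -80 mV.
#'
#' @param g_frac Activated receptor fraction.
#' @param V_pre Pyramidal membrane potential (mV).
#' @return Current density (uA/cm2).
#' @export
gaba_current <- function(g_frac, V_pre) {
  10 * g_frac * (V_pre + 80)
}

#' Steady-state mu-opioid receptor activation
#'
#' Hill dose-response `MOR_inf = 2 / (1 + (0.1/Morph)^1.2)` with the zero-dose
#' limit defined as 0.  The level saturates at 2; half of the maximum is
#' reached at 0.1 uM.
#'
#' @param Morph Morphine (or agonist) dose in uM, non-negative.
#' @return Steady-state activated receptor level in `[0, 2]`.
#' @export
mor_steady <- function(Morph) {
  if (any(Morph < 0)) stop("morphine dose must be non-negative")
  ifelse(Morph == 0, 0, 2 / (1 + (0.1 / Morph)^1.2))
}

#' GPCR / VGCC willing-state update
#'
#' The activated receptor level relaxes to its dose-dependent steady state
#' with a 1 s time constant; the willing-channel fraction follows
#' `dCaCh/dt = k_minus (1 - CaCh) - k_plus CaCh` with the voltage-dependent
#' return rate `k_minus = 0.3 / (1 + exp(-V_Int/5))` (G-beta-gamma unbinding
#' during depolarization) and the receptor-driven forward rate
#' `k_plus = 0.0006 MOR`.  With no drug, `k_plus = 0` and all channels end up
#' willing.
#'
#' @param state List with elements `MOR` and `CaCh`.
#' @param Morph Dose (uM).
#' @param V_Int Interneuron potential (mV).
#' @param dt Time step (ms).
#' @return Updated state list.
#' @export
gpcr_step <- function(state, Morph, V_Int, dt = 0.05) {
  stopifnot(dt > 0)
  mor_inf <- mor_steady(Morph)
  MOR <- state$MOR + dt * (mor_inf - state$MOR) / 1000
  k_minus <- 0.3 / (1 + exp(-V_Int / 5))
  k_plus <- 0.0006 * MOR
  CaCh <- state$CaCh + dt * (k_minus * (1 - state$CaCh) - k_plus * state$CaCh)
  list(MOR = MOR, CaCh = min(max(CaCh, 0), 1))
}

#' Morphine dose-response of the disinhibition chain
#'
#' Runs the deterministic presynaptic subsystem (pyramidal neuron,
#' interneuron, GABA_A gate, GPCR chain) once per dose under a common
#' stimulation protocol and summarizes the late-run willing-VGCC fraction and
#' the peak inhibitory current, plus the inhibition of that peak relative to
#' the zero-dose run.
#'
#' @param doses Numeric vector of doses (uM); must be non-empty and
#'   non-negative.  Include 0 to anchor the inhibition column (if absent, a
#'   0-dose reference run is added automatically).
#' @param protocol A [stimulus_protocol()].
#' @param duration_ms Run length (ms); the last 10 s define the late-run
#'   window.
#' @param dt Step size (ms).
#' @param params Model parameters.
#' @return A data frame with columns `dose_uM`, `vgcc_pct`,
#'   `ipsc_peak_uA_cm2`, `ipsc_inhibition_pct`.
#' @examples
#' \donttest{
#' dose_response_sweep(c(0, 0.1), duration_ms = 5000)
#' }
#' @export
dose_response_sweep <- function(doses, protocol = stimulus_protocol(),
                                duration_ms = 60000, dt = 0.05,
                                params = default_parameters()) {
  if (length(doses) == 0) stop("dose list must not be empty")
  if (any(doses < 0)) stop("doses must be non-negative")
  run_doses <- unique(c(0, doses))
  res <- lapply(run_doses, function(d) {
    cfg <- scenario_config(morphine_uM = d, label = sprintf("dose %.3g uM", d))
    tr <- run_simulation(cfg, protocol = protocol, dt = dt,
                         duration_ms = duration_ms, params = params,
                         presyn_only = TRUE)
    s <- attr(tr, "summary")
    # IPSC amplitude reported in the voltage-clamp convention: the peak
    # receptor activation times the driving force at the resting holding
    # potential (the convention of the experiments this chain is compared
    # against), not the instantaneous product during a spike.
    peak <- gaba_current(s$g_peak_late, -70)
    c(vgcc = 100 * s$cach_late_mean, peak = peak)
  })
  res <- do.call(rbind, res)
  ref_peak <- res[run_doses == 0, "peak"]
  out <- data.frame(
    dose_uM = run_doses,
    vgcc_pct = res[, "vgcc"],
    ipsc_peak_uA_cm2 = res[, "peak"],
    ipsc_inhibition_pct = 100 * (1 - res[, "peak"] / ref_peak)
  )
  out[match(doses, out$dose_uM), , drop = FALSE]
}
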