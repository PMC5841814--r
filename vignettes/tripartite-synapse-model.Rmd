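---
title: "The tripsyn model: opioid-modulated signalling at a tripartite CA3-CA1 synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tripsyn model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripsyn)
```

# The biological question

Opioids such as morphine induce a long-term potentiation (LTP)-like state at
hippocampal CA3-CA1 synapses that is thought to underlie drug-associated
memory. Three experimentally documented drug actions combine to produce it:

1. **Disinhibition.** Morphine activates mu-opioid receptors (muORs) on
   CA3 interneurons. The liberated G-beta-gamma subunits drive presynaptic
   N-type voltage-gated calcium channels (VGCCs) into a *reluctant* state,
   GABA release collapses, and the CA3 pyramidal cell escapes inhibition.
2. **Postsynaptic NMDAR facilitation.** Postsynaptic muOR activation both
   relieves the voltage-dependent Mg2+ block of NMDA receptors (the
   dissociation constant at 0 mV rises up to 4.8-fold, the electrical
   distance of the binding site by 0.11) and adds up to 15% to the
   voltage-independent NMDAR conductance.
3. **Astrocytic transporter depression.** Morphine halves the clearance rate
   of the astrocytic glutamate transporters (GLT-1), so cleft glutamate
   accumulates.

`tripsyn` implements the full closed loop: two Hodgkin-Huxley (H-H)
presynaptic neurons, stochastic vesicular glutamate release driven by a
five-site calcium sensor, an astrocyte with IP3/calcium dynamics and
threshold-gated gliotransmission, and a passive postsynaptic spine in which
calcium drives a CaMKII/PP1 phosphorylation ladder, an AMPAR-conductance
map, and a nitric-oxide (NO) retrograde signal back to the release sensor.

# Model structure

## Presynaptic neurons and the disinhibition chain

Both the pyramidal bouton and the interneuron are classic single-compartment
H-H neurons (gNa = 120, gK = 36, gL = 0.3 mS/cm2; reversals +45, -82,
-59.4 mV; resting potential near -70 mV), stimulated by a common pulse train
(default 10 uA/cm2, 5 Hz, 4 ms). The pyramidal cell additionally receives
`I_GABAA = 10 g (V_pre + 80)`, where the activated-receptor fraction `g`
relaxes (tau = 1 ms) toward a sigmoid of the interneuron potential whose
midpoint is shifted by the willing-VGCC fraction `CaCh`:
`g_inf = 1/(1 + exp(-(V_Int - 100 (1 - CaCh))/5))`. Receptor activation
follows the Hill curve `MOR_inf = 2/(1 + (0.1/Morph)^1.2)` with a 1 s
relaxation, and `CaCh` obeys a two-state willing/reluctant scheme with a
voltage-dependent return rate `k_minus = 0.3/(1 + exp(-V_Int/5))` and a
receptor-driven forward rate `k_plus = 0.0006 MOR`. With no drug every
channel ends up willing and the GABA gate opens fully on each interneuron
spike; with 1 uM morphine roughly forty percent of channels are reluctant at
protocol steady state and the gate barely opens.

**IPSC measurement convention.** The inhibitory current amplitude that
`dose_response_sweep()` reports is the peak receptor activation times the
driving force at the resting potential, `10 g_peak (-70 + 80)` -- the
voltage-clamp convention of the slice experiments this chain is calibrated
against. The instantaneous product `10 g (V_pre + 80)` spikes much higher
whenever an action potential coincides with an open gate; that quantity is
recorded in the trace but is not an IPSC amplitude in the experimental
sense.

## Release machinery

Calcium at the release site has a fast and a slow component. The fast
component is the AP-driven microdomain transient: a two-gate N-type channel
(Boltzmann activation, tau 1 ms) into a 0.13 um3 bouton, cleared by a
Hill-type PMCA pump and balanced by a membrane leak whose rate is fixed so
that 0.1 uM is the exact resting point. The slow component is a Li-Rinzel
store oscillator (IP3R channel flux, SERCA pump, ER leak) whose IP3 is
produced downstream of gliotransmitter binding. The store subsystem is gated
by the *bulk* calcium `c_rest + c_slow`: the ER does not see the
few-millisecond microdomain transient that drives the sensor, and gating it
on the total would inactivate the IP3R gate spuriously during every spike.

Evoked release uses the five-site sensor chain
`X = X1 = ... = X5 = X5*` with forward rates `(5-k) alpha c`, backward rates
`k beta` and a calcium-independent isomerization into the releasable isomer.
Each of the two docked vesicles carries an independent sensor simulated as
an exact continuous-time Markov chain within each Euler step (rates frozen
at the step start). A vesicle reaching `X5*` triggers release with
`f_r = n_ready/2`; spontaneous release is a Poisson process with the
sigmoidal rate `lambda(c) = 0.85/(1 + exp((50 - c)/5))` per ms, gated to
non-depolarized membrane (`V_pre < -55 mV`), with `f_r = 0.5`. Any release
sets a 6.34 ms refractory window. Vesicle pools follow
`dR/dt = I/tau_rec - f_r R`, `dE/dt = -E/tau_inac + f_r R` with
tau_rec = 800 ms, tau_inac = 3 ms, and the release event applied as a
discrete R-to-E transfer (the Tsodyks-Markram convention; spreading
`f_r` over a single 0.05 ms Euler step would release a few percent of a
vesicle per event, which contradicts the two-vesicle bookkeeping). Cleft
glutamate obeys `d glut/dt = 2 * 60 uM * E - 10 glt_factor glut` per ms;
`glt_factor` (1 normal, 0.5 under morphine, 1.5 stimulated) is the single
point through which the transporter effect enters.

**Spontaneous-release microdomain offset.** The printed spontaneous-rate
constants place the half-maximum at 50 uM, which is unreachable from a
0.1 uM resting bouton; the source models calibrate the machinery so that
spontaneous release runs at 1-3 Hz. We therefore give the release site a
documented resting microdomain level `c_md0` (16.2 uM, applied to the
spontaneous-rate input only) chosen once from that published calibration;
the quiescent-run spontaneous frequency lands in the lower half of the
1-3 Hz band, and the store-driven slow calcium modulates it upward in
active runs.

## Astrocyte

Cleft glutamate drives astrocytic IP3 production through a saturable
mGluR/PLC-beta term (severed entirely when the mGluR flag is off),
supplemented by calcium-modulated PLC-delta and degraded by IP3-3K and
IP-5P. Calcium follows the Li-Rinzel scheme with the dynamic inactivation
gate cubed inside the channel flux (the gate would otherwise be dead code),
and the ER pool follows from conservation of total free calcium at the
fixed ER/cytosol volume ratio. Three independent calcium-binding gates
license vesicle fusion (`Pr_a = O1 O2 O3`); release requires cytosolic
calcium to *strictly* exceed 196.69 nM (the Heaviside factor is zero at
equality), drains an R/E/I pool with the same 800/3 ms constants, and the
extrasynaptic gliotransmitter integrates production
`12 * 20 mM * kappa_a * E_a` against 10/ms clearance. `kappa_a` is the one
documented scale constant converting the millimolar vesicular content to
the extrasynaptic micromolar range (a vesicular-to-extrasynaptic volume
ratio); it was fixed once so that gliotransmitter transients sit in the
low-micromolar regime that engages the presynaptic receptors.

## Postsynaptic spine

The spine is passive: `tau_post dV/dt = -(V - V_rest) + R_m I_syn` with
`I_syn = -(I_AMPA + I_NMDA)`. AMPAR gating is driven by
`0.42 glut + 0.01 g_a`; its conductance comes from the plasticity map
below. NMDAR gating is driven by `k1 glut + k2 g_a`; its conductance is
`g_VI + 0.15 H(Morph) + g_VD` where `H` is the muOR occupancy Hill term and
`g_VD` relaxes toward `k (V - V0)` (clipped at zero); the current carries
the Mg2+ unblock factor
`1/(1 + [Mg]0 (k0 + 15.58 H)^{-1} exp(-z (delta + 0.11 H) F V / RT))`.
The baseline `k0 = 15.58/3.8` is forced by the requirement that the
saturating dissociation-constant increase be exactly 4.8-fold; with
`z = 2`, `delta = 0.8` the drug-free block matches the classic
hippocampal voltage dependence. The 0.11 increment is applied as an
absolute shift of the electrical distance (reading the operative formula
literally; the "11%" phrasing is exact only for a baseline distance of 1).

Spine calcium integrates weighted receptor currents (0.012 AMPAR,
0.06 NMDAR) and a stochastic L-type leak (`g_L B(N, P_open) (V - 27.4)`
with a per-step binomial draw of open channels), against a
`k_s (c - 0.1 uM)` pump, all divided by the endogenous-buffer factor
`1 + b_t K_endo/(K_endo + c)^2` exactly as the calcium balance is written.
CaMKII phosphorylation uses the 11-state ladder with the ring coefficient
pattern (1, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1 on the
autophosphorylation rate and `i` on dephosphorylation), coupled to the
PP1/inhibitor-1 pool (PKA phosphorylation, calcineurin dephosphorylation
with a cubic calcium Hill term, PP1-I1P binding). All literature rates are
per second and are converted to per millisecond at load time; unit tags are
checked programmatically because silent s/ms mixing is the likeliest
reproduction failure for this model. `Ph.CaMKII` is the plain sum
`P1 + ... + P10`; the Michaelis denominator of the dephosphorylation rate
uses the weighted sum `sum(i * P_i)`, and the two are kept distinct.

The AMPAR conductance map treats kinase and phosphatase activities as Hill
functions of `Ph.CaMKII` (`EP = 1 + 30 ph^2/(1 + ph^2)`,
`EK = 1 + 100 ph^2/(8^2 + ph^2)`; the flattened source text's "82" is read
as 8 squared, consistent with the printed asymptote of 101) and reduces in
closed form to `g/A_T = ((EP + 2 EK)/(EP + EK))^2`, running from 9/4 at
zero phosphorylation through a transient depression around
ph of order 1 uM to 54289/17424 at saturation -- a ~38.6% ceiling, with the
pathological working point reaching about +30%. The NO feedback is the
sigmoid increment `0.005/(1 + exp(-(ph - 40) * 0.4))` applied uniformly to
all five calcium-binding steps of the release sensor on the following time
step (the source describes a uniform increase in binding capability; with a
0.5% ceiling the choice is numerically inconsequential, but it is flagged
here for sensitivity analysis).

# Scenarios

`build_scenario(id)` returns the thirteen-entry intervention registry:
S1 is the full pathological condition (1 uM morphine; both muOR populations
active, mGluR active, gliotransmission on, transporter clearance halved),
S2-S12 disable or counteract individual pathways (presynaptic muOR,
postsynaptic muOR, mGluR, gliotransmission, transporter scaling at 1.0 or
1.5, and their combinations), and S13 is the drug-free normal condition.
Disabling the presynaptic muOR pins receptor activation at zero, so the
willing fraction returns to one and inhibition is normal; disabling the
postsynaptic muOR zeroes the dose seen by the Mg-block and conductance
increments only.

# Numerical scheme

* Fixed-step forward Euler, reference `dt = 0.05 ms`; larger steps trigger
  a stability warning (the H-H spike is the stiffest component). A
  dt-halving check on the deterministic subsystem holds to better than 2%.
* Update order within a step: neurons; GPCR/GABA gate; presynaptic calcium;
  release machinery; cleft glutamate; astrocyte; gliotransmitter; spine;
  CaMKII/plasticity; the NO boost computed from the new phosphorylation
  acts on the next step. All couplings use previous-step values.
* Stochastic draws come from three xoshiro256++ sub-streams (sensor chain,
  spontaneous Poisson, postsynaptic channel binomial) derived from the
  master seed with splitmix64, so toggling one noise source leaves the
  others' draws untouched and a fixed seed reproduces a trace bit for bit.
* The sensor chain advances by exact Gillespie transitions inside each
  Euler step with rates frozen at the step start; a mean-field master
  equation oracle (`ladder_oracle()`) validates the ensemble statistics.
* Before `t = 0` the system relaxes for 2 s with no stimulus and no drug,
  so every run starts from its numerically found resting state; summary
  statistics exclude a further 5 s burn-in after stimulation starts.
* Degenerate inputs: concentrations are clamped at zero where Euler
  undershoot could make them negative; `Theta(0) = 0` at the astrocytic
  release threshold; the removable singularities of the H-H rate functions
  are evaluated by their limits; non-finite state aborts the run naming the
  trace column and time.

# Parameter provenance and calibration

Every constant lives in `default_parameters()` with units and a provenance
tag. `printed` constants come directly from the model equations. Constants
tagged `source-model` are standard values of the upstream component models
(H-H kinetics, Li-Rinzel/IP3R constants d1-d5 and a2, the astrocytic IP3
pathway rates, the five-site sensor rates, the CaMKII/PP1 rates, the
Jahr-Stevens-type Mg block). The remaining scale constants are tagged
`calibrated`: the model equations leave them free, and they were fixed
*once* so that the drug-free run sits in the documented normal operating
regime -- AP-locked microdomain transients of tens of micromolar with
near-threshold evoked release, spontaneous release in the 1-3 Hz band,
sparse astrocytic calcium oscillations crossing the release threshold, and
a postsynaptic phosphorylation level that approaches the NO threshold only
late in a normal run while the pathological run crosses it early. They
were not revisited afterwards. The most influential ones are the
single-channel N-type conductance (evoked-release margin), the mGluR IP3
production rate (astrocytic oscillation frequency), the gliotransmitter
volume ratio `kappa_a`, the presynaptic store size `c0_pre`, and the NMDAR
gating scale (postsynaptic calcium regime).

# What the simulated conditions do and do not capture

The scenarios reproduce the *structure* of the study conditions: one
synapse, one astrocyte, the standard 60-s pulse-train protocol, and on/off
interventions on each drug pathway. They do not emulate spatial transmitter
diffusion, multi-synapse or astrocyte-network effects, interneuron-astrocyte
coupling, receptor desensitization beyond the modeled gates, or LTD/STDP;
those are outside the model's scope by design. Passing tests therefore show
that the implemented signalling chain behaves as specified under these
idealized conditions, not that real tissue does.

Two quantitative limitations of the calibrated model are worth stating
plainly, because the test suite reports them honestly as failures rather
than hiding them. First, the 800 ms vesicle-recovery constant caps the
sustained release flux, so with spontaneous release held inside its 1-3 Hz
band the pathological-to-normal glutamate ratio saturates near three; the
larger contrast reported for the original simulations is not reachable at
these printed pool constants. Second, the normal condition's slow passage
of the AMPAR map through its transient-depression region keeps the
conductance ratio above the reported value of roughly 1.3 whenever the
phosphorylation ratio is held near 4; the two readouts are coupled through
the same map and cannot be matched simultaneously. The gliotransmitter
contrast lands between the two inconsistent figures reported for it (2.5x
and 4.5x), close to the 250% description.

# Problem sizes

The unit suite runs second-scale subsets (5-20 s simulated time) of the
standard protocol plus millisecond-scale clamp fixtures; the reproduction
checks run the full 60-s protocol, with the stochastic scenario comparison
averaged over twenty-five seeds (the normal condition's phosphorylation
switch time varies strongly across seeds, so the factor means need a
wide seed average to stabilize). A 60-s full-model run integrates 1.2 million
steps and takes on the order of a second on one core.

# Session info

```{r}
sessionInfo()
```
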