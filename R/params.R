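#' Default model parameters
#'
#' Builds the full parameter set of the tripartite-synapse model as a
#' `tripsyn_params` object: a named numeric vector of values plus per-parameter
#' units and a provenance tag.  Tags are `"printed"` for constants written in
#' the model equations themselves, `"source-model"` for constants taken from
#' the upstream model literature the synapse model builds on (Hodgkin-Huxley
#' kinetics, Li-Rinzel/IP3R calcium dynamics, the five-site release sensor,
#' the astrocytic IP3 pathway, the CaMKII/PP1 switch, Jahr-Stevens style Mg
#' block), and `"calibrated"` for scale constants that the printed equations
#' leave free and that were fixed once so the drug-free run sits in the
#' documented normal operating regime (see the methods vignette).
#'
#' All rates are stored in per-millisecond units; concentrations in uM,
#' voltages in mV, currents in pA (spine) or uA/cm2 (neurons), conductances
#' in nS.
#'
#' @return An object of class `tripsyn_params` with elements `values`
#'   (named numeric), `units` and `source` (named character).
#' @examples
#' p <- default_parameters()
#' p$values[["tau_g"]]
#' @export
default_parameters <- function() {
  if (!is.null(.param_cache$defaults)) return(.param_cache$defaults)
  rows <- list(
    # ---- presynaptic neurons / GABA_A / GPCR chain (printed equations) ----
    list("g_gaba_max", 10,      "uA/cm2 per mV", "printed"),
    list("v_gaba",     -80,     "mV",            "printed"),
    list("tau_g",      1,       "ms",            "printed"),
    list("tau_mor",    1000,    "ms",            "printed"),
    list("mor_max",    2,       "dimensionless", "printed"),
    list("mor_kd",     0.1,     "uM",            "printed"),
    list("mor_hill",   1.2,     "dimensionless", "printed"),
    list("k_minus_max",   0.3,    "1/ms", "printed"),
    list("k_minus_slope", 5,      "mV",   "printed"),
    list("k_plus_coef",   0.0006, "1/ms", "printed"),

    # ---- fast presynaptic calcium (N-type / PMCA / leak) ----
    list("rho_ca",      3.2,   "channels/um2", "source-model"),
    list("a_btn",       1.24,  "um2",          "source-model"),
    list("g_ca_single", 0.9,   "pS",           "calibrated"),
    list("ca_conv_btn", 1e-9 / (2 * 96487 * 0.13e-15), "uM/ms per pA",
         "derived: 1/(z F V_btn), V_btn = 0.13 um3"),
    list("c_ext",   2000, "uM", "source-model"),
    list("c_rest",  0.1,  "uM", "source-model"),
    list("v_mca",   -17,  "mV", "source-model"),
    list("k_mca",   8.4,  "mV", "source-model"),
    list("tau_mca", 1,    "ms", "calibrated"),
    list("nu_pmca", 3.0,  "uM/ms", "calibrated"),
    list("k_pmca",  0.2,  "uM",    "source-model"),
    # leak fixed so that c_rest is the exact pump/leak balance point
    list("nu_leak", 3.0 * 0.1^2 / (0.1^2 + 0.2^2) / (2000 - 0.1),
         "1/ms", "derived: rest balance"),
    list("rt_zf", 8.314 * 310 / (2 * 96487) * 1000, "mV",
         "derived: RT/zF at 310 K"),

    # ---- slow presynaptic calcium (Li-Rinzel + gliotransmitter-driven IP3) --
    list("c1",   0.185,   "dimensionless", "source-model"),
    list("nu1",  0.006,   "1/ms",          "source-model"),
    list("nu2",  1.1e-4,  "1/ms",          "source-model"),
    list("nu3",  9e-4,    "uM/ms",         "source-model"),
    list("k3",   0.1,     "uM",            "source-model"),
    list("c0_pre", 6,     "uM",            "calibrated"),
    list("d1",   0.13,    "uM",            "source-model"),
    list("d2",   1.049,   "uM",            "source-model"),
    list("d3",   0.9434,  "uM",            "source-model"),
    list("d5",   0.08234, "uM",            "source-model"),
    list("a2",   2e-4,    "1/(uM ms)",     "source-model"),
    list("nu_g", 3e-3,    "uM/ms",         "calibrated"),
    list("k_g",  0.8,     "uM",            "calibrated"),
    list("tau_p", 2e-4,   "1/ms",          "calibrated"),
    list("p0",   0.16,    "uM",            "source-model"),

    # ---- five-site release sensor / vesicle pools / cleft glutamate ----
    list("sensor_alpha", 0.3, "1/(uM ms)", "source-model"),
    list("sensor_beta",  3,   "1/ms",      "source-model"),
    list("sensor_gamma", 30,  "1/ms",      "source-model"),
    list("sensor_delta", 8,   "1/ms",      "source-model"),
    list("t_refractory", 6.34, "ms",       "printed"),
    list("tau_rec",  800, "ms", "printed"),
    list("tau_inac", 3,   "ms", "printed"),
    list("spont_a1", 50,   "uM",   "printed"),
    list("spont_a2", 5,    "uM",   "printed"),
    list("spont_a3", 0.85, "1/ms", "printed"),
    list("c_md0", 16.2, "uM", "calibrated: published 1-3 Hz spontaneous rate"),
    list("v_spont_gate", -55, "mV", "calibrated"),
    list("n_v", 2,  "vesicles", "printed"),
    list("g_v", 60, "uM",       "printed"),
    list("g_c", 10, "1/ms",     "printed"),

    # ---- astrocyte ----
    list("nu_beta",  1.3e-3, "uM/ms", "calibrated"),
    list("K_R",      1.3,  "uM",    "source-model"),
    list("K_p",      10,   "uM",    "source-model"),
    list("K_pi",     0.6,  "uM",    "source-model"),
    list("nu_delta", 2e-5, "uM/ms", "source-model"),
    list("k_delta",  1.5,  "uM",    "source-model"),
    list("K_plcd",   0.1,  "uM",    "source-model"),
    list("nu_3k",    2e-3, "uM/ms", "source-model"),
    list("K_D",      0.7,  "uM",    "source-model"),
    list("K_3",      1,    "uM",    "source-model"),
    list("r_5",      4e-5, "1/ms",  "source-model"),
    list("c1a",  0.185,  "dimensionless", "source-model"),
    list("r_ca", 0.006,  "1/ms",          "source-model"),
    list("r_l",  1.1e-4, "1/ms",          "source-model"),
    list("v_er", 9e-4,   "uM/ms",         "source-model"),
    list("K_er", 0.1,    "uM",            "source-model"),
    list("d1a", 0.13,    "uM",        "source-model"),
    list("d2a", 1.049,   "uM",        "source-model"),
    list("d3a", 0.9434,  "uM",        "source-model"),
    list("d5a", 0.08234, "uM",        "source-model"),
    list("a2a", 2e-4,    "1/(uM ms)", "source-model"),
    list("c_tot_a", 2, "uM", "source-model"),
    list("c_thresh", 0.19669, "uM", "printed"),
    list("tau_rec_a",   800, "ms", "printed"),
    list("tau_inact_a", 3,   "ms", "printed"),
    list("k1_plus",  3.75e-3, "1/(uM ms)", "printed"),
    list("k1_minus", 4e-4,    "1/ms",      "printed"),
    list("k2_plus",  2.5e-3,  "1/(uM ms)", "printed"),
    list("k2_minus", 1e-3,    "1/ms",      "printed"),
    list("k3_plus",  1.25e-2, "1/(uM ms)", "printed"),
    list("k3_minus", 1e-3,    "1/ms",      "printed"),
    list("n_v_a", 12,    "vesicles", "printed"),
    list("g_v_a", 20000, "uM",       "printed"),
    list("kappa_a", 0.005, "dimensionless",
         "calibrated: vesicular-to-extrasynaptic volume ratio"),
    list("g_c_a", 10, "1/ms", "printed"),

    # ---- postsynaptic spine ----
    list("tau_post",    10,  "ms", "source-model"),
    list("v_rest_post", -70, "mV", "source-model"),
    list("r_m",         0.5, "GOhm", "source-model"),
    list("v_ampa", 0, "mV", "source-model"),
    list("v_nmda", 0, "mV", "source-model"),
    list("alpha_ampa", 0.11,   "1/(uM ms)", "calibrated"),
    list("beta_ampa",  0.19,   "1/ms",      "source-model"),
    list("a1_ampa", 0.42, "dimensionless", "printed"),
    list("a2_ampa", 0.01, "dimensionless", "printed"),
    list("alpha_nmda", 1.2e-3, "1/(uM ms)", "calibrated"),
    list("beta_nmda",  0.0066, "1/ms",      "source-model"),
    list("k1_nmda", 1.0, "dimensionless", "calibrated"),
    list("k2_nmda", 0.5, "dimensionless", "calibrated"),
    list("g_vi", 1.0, "nS",
         "derived: +0.15 nS morphine increment = the reported 15% rise"),
    list("g_nmda_morph_inc", 0.15, "nS", "printed"),
    list("k_gvd",   0.01, "nS/mV", "calibrated"),
    list("v0_gvd",  -70,  "mV",    "calibrated"),
    list("tau_gvd", 5,    "ms",    "source-model"),
    list("mg0",   1, "mM", "source-model"),
    list("k0_mg", 15.58 / 3.8, "mM",
         "derived: 4.8-fold saturating K0 increase with +15.58 increment"),
    list("mg_k_inc", 15.58, "mM", "printed"),
    list("z_mg",     2,     "dimensionless", "source-model"),
    list("delta_mg", 0.8,   "dimensionless", "source-model"),
    list("delta_mg_inc", 0.11, "dimensionless", "printed"),
    list("f_rt", 96487 / (8.314 * 310 * 1000), "1/mV",
         "derived: F/RT at 310 K"),
    list("s_ampa", 1.5, "nS per map unit", "calibrated"),

    # ---- postsynaptic calcium ----
    list("eta",        0.012, "dimensionless", "printed"),
    list("gamma_nmda", 0.06,  "dimensionless", "printed"),
    list("ca_conv_spine", 1e-9 / (2 * 96487 * 0.9048e-15), "uM/ms per pA",
         "derived: 1/(z F V_spine), V_spine = 0.9048 um3"),
    list("k_s", 0.1, "1/ms", "printed"),
    list("c_post_rest", 0.1, "uM", "printed"),
    list("b_t",    200, "uM", "printed"),
    list("k_endo", 10,  "uM", "printed"),
    list("g_l_ca", 0.015, "nS", "printed"),
    list("n_chan", 4,     "channels",      "calibrated"),
    list("p_open", 5e-5,  "dimensionless", "calibrated"),
    list("v_l_ca", 27.4,  "mV", "printed"),

    # ---- CaMKII / PP1 (literature rates are per second; stored per ms) ----
    list("camkii_total", 80, "uM", "derived: 2 x P_half"),
    list("k1_cam", 0.5e-3, "1/ms",      "printed"),
    list("K_H1",   4,      "uM",        "printed"),
    list("k2_cam", 10e-3,  "1/ms",      "printed"),
    list("K_M",    20,     "uM",        "printed"),
    list("ep0", 0.1, "uM", "printed"),
    list("i0",  0.1, "uM", "printed"),
    list("k3_cam", 1e-3, "1/(uM ms)", "printed"),
    list("k4_cam", 1e-6, "1/ms",      "printed"),
    list("nu_pka", 0.45e-3, "uM/ms", "printed"),
    list("nu_can", 2e-3,    "1/ms",  "printed"),
    list("K_H2",   0.7,     "uM",    "printed"),

    # ---- NO feedback and AMPAR conductance map ----
    list("p_half", 40,    "uM",    "printed"),
    list("k_half", 0.4,   "1/uM",  "printed"),
    list("k_syt",  0.005, "dimensionless", "printed"),
    list("ep_max", 30,  "dimensionless", "printed"),
    list("ep_K",   1,   "uM",            "printed"),
    list("ek_max", 100, "dimensionless", "printed"),
    list("ek_K",   8,   "uM",            "printed"),
    list("a_t",    1,   "map units",     "printed")
  )
  values <- vapply(rows, function(r) as.numeric(r[[2]]), numeric(1))
  names(values) <- vapply(rows, function(r) r[[1]], character(1))
  units <- vapply(rows, function(r) r[[3]], character(1))
  src <- vapply(rows, function(r) r[[4]], character(1))
  names(units) <- names(src) <- names(values)
  .param_cache$defaults <- structure(
    list(values = values, units = units, source = src),
    class = "tripsyn_params")
  .param_cache$defaults
}

.param_cache <- new.env(parent = emptyenv())

#' @export
print.tripsyn_params <- function(x, ...) {
  cat("tripsyn model parameters:", length(x$values), "constants\n")
  tab <- table(sub(":.*$", "", x$source))
  for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Convert a parameter object to a data frame
#'
#' @param x A `tripsyn_params` object.
#' @param row.names,optional,... Passed through for S3 compatibility; unused.
#' @return A data frame with columns `name`, `value`, `units`, `source`.
#' @export
as.data.frame.tripsyn_params <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(name = names(x$values), value = unname(x$values),
             units = unname(x$units), source = unname(x$source),
             stringsAsFactors = FALSE)
}

#' Write / read a parameter file
#'
#' Parameters are stored as JSON with one entry per constant (name, value,
#' units, source) so that a run's parameter provenance travels with it.
#'
#' @param params A `tripsyn_params` object.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `tripsyn_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tripsyn_params"))
  jsonlite::write_json(as.data.frame(params), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("name", "value", "units", "source")
  if (!all(required %in% names(df)))
    stop("parameter file is missing columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  values <- as.numeric(df$value)
  names(values) <- df$name
  units <- df$units; src <- df$source
  names(units) <- names(src) <- df$name
  validate_parameters(structure(
    list(values = values, units = units, source = src),
    class = "tripsyn_params"))
}

#' Validate a parameter object against the default registry
#'
#' Checks that every constant the integrator needs is present and finite and
#' that no unit tag changed relative to the registry (silent s/ms mixing is
#' the likeliest reproduction failure for this model, so unit tags are
#' checked programmatically).
#'
#' @param params A `tripsyn_params` object.
#' @return `params`, invisibly, after checks.
#' @export
validate_parameters <- function(params) {
  ref <- default_parameters()
  missing <- setdiff(names(ref$values), names(params$values))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  if (any(!is.finite(params$values)))
    stop("non-finite parameter value(s): ",
         paste(names(params$values)[!is.finite(params$values)], collapse = ", "))
  common <- intersect(names(ref$units), names(params$units))
  bad <- common[params$units[common] != ref$units[common]]
  if (length(bad) > 0)
    stop("unit mismatch for: ", paste(bad, collapse = ", "))
  invisible(params)
}

#' Stable content hash of a parameter set
#'
#' Polynomial rolling hash over the sorted name=value pairs; stored in trace
#' metadata so that a trace can be tied to the exact constants that produced
#' it.
#'
#' @param params A `tripsyn_params` object.
#' @return A character scalar (hex).
#' @export
param_hash <- function(params) {
  stopifnot(inherits(params, "tripsyn_params"))
  v <- params$values[order(names(params$values))]
  # 15 significant digits: stable across JSON round trips, still sensitive
  # to any real change of a constant
  txt <- paste(names(v), formatC(v, digits = 15, format = "g"),
               sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
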