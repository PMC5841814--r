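#' Stimulation protocol
#'
#' A rectangular pulse train: `amplitude` is applied during the first
#' `width_ms` of every `1000/freq_hz` period.  The default is the standard
#' protocol of the study conditions: 10 uA/cm2, 5 Hz, 4 ms pulses.
#'
#' @param amplitude_uA_cm2 Pulse amplitude (uA/cm2).
#' @param freq_hz Pulse frequency (Hz).
#' @param width_ms Pulse width (ms); must be shorter than the period.
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(amplitude_uA_cm2 = 10, freq_hz = 5,
                              width_ms = 4) {
  stopifnot(amplitude_uA_cm2 >= 0, freq_hz > 0, width_ms > 0,
            width_ms < 1000 / freq_hz)
  structure(list(amplitude_uA_cm2 = amplitude_uA_cm2, freq_hz = freq_hz,
                 width_ms = width_ms), class = "stimulus_protocol")
}

#' Stimulus value at a time point
#'
#' @param t Time (ms), non-negative; vectorized.
#' @param protocol A [stimulus_protocol()].
#' @return Current density (uA/cm2) at each `t`.
#' @export
stimulus <- function(t, protocol = stimulus_protocol()) {
  stopifnot(all(t >= 0))
  period <- 1000 / protocol$freq_hz
  ifelse(t %% period < protocol$width_ms, protocol$amplitude_uA_cm2, 0)
}

#' Scenario configuration
#'
#' The switchboard of drug effects: dose, the two mu-opioid receptor
#' populations, the astrocytic metabotropic receptor pathway,
#' gliotransmission, and the glutamate-transporter clearance scaling.
#'
#' @param morphine_uM Dose (uM), non-negative.
#' @param presyn_mu_or_on,postsyn_mu_or_on,astro_mglur_on,gliotransmission_on
#'   Logical flags.
#' @param glt_factor Clearance scaling (> 0): 1 normal, 0.5 under morphine,
#'   1.5 when the transporters are stimulated.
#' @param label Scenario name.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(morphine_uM = 0, presyn_mu_or_on = TRUE,
                            postsyn_mu_or_on = TRUE, astro_mglur_on = TRUE,
                            gliotransmission_on = TRUE, glt_factor = 1,
                            label = "custom") {
  stopifnot(morphine_uM >= 0, glt_factor > 0)
  structure(list(morphine_uM = morphine_uM,
                 presyn_mu_or_on = isTRUE(presyn_mu_or_on),
                 postsyn_mu_or_on = isTRUE(postsyn_mu_or_on),
                 astro_mglur_on = isTRUE(astro_mglur_on),
                 gliotransmission_on = isTRUE(gliotransmission_on),
                 glt_factor = glt_factor, label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s': morphine %.3g uM, glt x%.2g\n", x$label,
              x$morphine_uM, x$glt_factor))
  cat(sprintf("  presyn muOR %s | postsyn muOR %s | mGluR %s | gliotransmission %s\n",
              ifelse(x$presyn_mu_or_on, "on", "off"),
              ifelse(x$postsyn_mu_or_on, "on", "off"),
              ifelse(x$astro_mglur_on, "on", "off"),
              ifelse(x$gliotransmission_on, "on", "off")))
  invisible(x)
}

#' The thirteen intervention scenarios
#'
#' Registry of the simulation battery: scenario 1 is the full pathological
#' condition (all morphine effects on), scenarios 2-12 switch off or
#' counteract individual pathways, and scenario 13 is the drug-free normal
#' condition.
#'
#' @param id Scenario number, 1..13.
#' @param morphine_uM Dose for the drug scenarios (uM); scenario 13 always
#'   runs at 0.
#' @return A [scenario_config()].
#' @examples
#' build_scenario(1)
#' build_scenario(13)
#' @export
build_scenario <- function(id, morphine_uM = 1) {
  if (length(id) != 1 || !(id %in% 1:13))
    stop("scenario id must be a single integer in 1..13")
  base <- list(morphine_uM = morphine_uM, presyn = TRUE, postsyn = TRUE,
               mglur = TRUE, glio = TRUE, glt = 0.5)
  s <- switch(as.character(id),
    "1" = base,
    "2" = modifyList(base, list(presyn = FALSE)),
    "3" = modifyList(base, list(postsyn = FALSE)),
    "4" = modifyList(base, list(presyn = FALSE, postsyn = FALSE)),
    "5" = modifyList(base, list(glio = FALSE)),
    "6" = modifyList(base, list(glt = 1.0)),
    "7" = modifyList(base, list(glt = 1.5)),
    "8" = modifyList(base, list(mglur = FALSE)),
    "9" = modifyList(base, list(mglur = FALSE, postsyn = FALSE)),
    "10" = modifyList(base, list(mglur = FALSE, glt = 1.5)),
    "11" = modifyList(base, list(postsyn = FALSE, glt = 1.5)),
    "12" = modifyList(base, list(postsyn = FALSE, mglur = FALSE, glt = 1.5)),
    "13" = list(morphine_uM = 0, presyn = TRUE, postsyn = TRUE, mglur = TRUE,
                glio = TRUE, glt = 1.0)
  )
  scenario_config(morphine_uM = s$morphine_uM, presyn_mu_or_on = s$presyn,
                  postsyn_mu_or_on = s$postsyn, astro_mglur_on = s$mglur,
                  gliotransmission_on = s$glio, glt_factor = s$glt,
                  label = sprintf("S%d", id))
}

#' Run the coupled simulation
#'
#' Integrates the full tripartite-synapse model (or the deterministic
#' presynaptic subsystem only) with fixed-step forward Euler in the
#' documented update order: neurons, GPCR/GABA gate, presynaptic calcium,
#' release machinery, cleft glutamate, astrocyte, gliotransmitter, spine,
#' CaMKII/plasticity; the NO feedback computed at a step acts on the next.
#' All stochastic draws (sensor chain, spontaneous release, postsynaptic
#' channel openings) come from three independent sub-streams derived from
#' `seed`, so a fixed seed reproduces the trace bit-identically.
#'
#' Before `t = 0` the system is relaxed for `settle_ms` with no stimulation
#' and no drug, so the run starts from its numerically found resting state.
#'
#' @param config A [scenario_config()] (or [build_scenario()] output).
#' @param protocol A [stimulus_protocol()] applied to both presynaptic
#'   neurons.
#' @param dt Step size (ms); 0.05 is the reference value, larger values
#'   trigger a stability warning.
#' @param duration_ms Simulated time (ms).
#' @param seed Master seed (integer).
#' @param settle_ms Drug-free, stimulus-free relaxation before t = 0 (ms).
#' @param record_dt Trace sampling interval (ms); must be a multiple of
#'   `dt`.
#' @param presyn_only If `TRUE`, integrate only the deterministic
#'   presynaptic subsystem (neurons + GPCR + GABA); downstream columns stay
#'   at their initial values.
#' @param no_feedback If `TRUE`, sever the NO retrograde boost (used for
#'   decoupling tests).
#' @param burn_in_ms Samples before this time are excluded from the summary
#'   means stored in the trace attributes.
#' @param params Model parameters.
#' @return A `sim_trace`: a data frame with one row per recorded sample and
#'   the documented trace columns, with metadata attributes `config`,
#'   `protocol`, `dt`, `seed`, `param_hash` and `summary` (late-run IPSC
#'   peak and willing-VGCC mean, monitoring-factor means, event and spike
#'   counts).
#' @examples
#' \donttest{
#' tr <- run_simulation(build_scenario(13), duration_ms = 2000, seed = 1)
#' attr(tr, "summary")$spikes_pre
#' }
#' @export
run_simulation <- function(config, protocol = stimulus_protocol(),
                           dt = 0.05, duration_ms = 60000, seed = 1,
                           settle_ms = 2000, record_dt = 1,
                           presyn_only = FALSE, no_feedback = FALSE,
                           burn_in_ms = 5000,
                           params = default_parameters()) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(protocol, "stimulus_protocol"), dt > 0,
            duration_ms >= 0)
  validate_parameters(params)
  if (dt > 0.05)
    warning("dt > 0.05 ms: forward Euler may be unstable for the H-H spikes")
  stride <- max(1L, as.integer(round(record_dt / dt)))
  res <- .sim_core_cpp(unclass(params), unclass(config), unclass(protocol),
                       dt, duration_ms, settle_ms, as.numeric(seed),
                       stride, presyn_only, no_feedback, burn_in_ms)
  tr <- as.data.frame(res$trace)
  attr(tr, "config") <- config
  attr(tr, "protocol") <- protocol
  attr(tr, "dt") <- dt
  attr(tr, "record_dt") <- stride * dt
  attr(tr, "seed") <- seed
  attr(tr, "settle_ms") <- settle_ms
  attr(tr, "burn_in_ms") <- burn_in_ms
  attr(tr, "param_hash") <- param_hash(params)
  attr(tr, "summary") <- res[setdiff(names(res), "trace")]
  class(tr) <- c("sim_trace", "data.frame")
  tr
}

#' @export
print.sim_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("sim_trace: %d samples x %d columns (%.3g s at record_dt = %g ms)\n",
              nrow(x), ncol(x), max(x$t_ms) / 1000, attr(x, "record_dt")))
  if (!is.null(cfg)) print(cfg)
  s <- attr(x, "summary")
  if (!is.null(s) && is.finite(s$mean_glut))
    cat(sprintf("  means after burn-in: glut %.3g uM | glio %.3g uM | Ph.CaMKII %.3g uM | gAMPA %.3g nS\n",
                s$mean_glut, s$mean_glio, s$mean_ph_camkii, s$mean_g_ampa))
  invisible(x)
}

#' Write / read a simulation trace
#'
#' Traces are stored as plain CSV with a commented metadata header
#' (`# key: value` lines covering seed, dt, scenario flags and the parameter
#' hash) so that a file is sufficient to reproduce its run.  Values are
#' written at full precision; the round trip is lossless.
#'
#' @param trace A `sim_trace`.
#' @param path File path.
#' @param every Keep every `every`-th sample on write (downsampling
#'   preserves columns and metadata).
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   `sim_trace`.
#' @export
write_trace <- function(trace, path, every = 1L) {
  stopifnot(inherits(trace, "sim_trace"), every >= 1)
  cfg <- attr(trace, "config")
  meta <- c(
    format_version = "1",
    seed = attr(trace, "seed"),
    dt = attr(trace, "dt"),
    record_dt = attr(trace, "record_dt") * every,
    settle_ms = attr(trace, "settle_ms"),
    burn_in_ms = attr(trace, "burn_in_ms"),
    param_hash = attr(trace, "param_hash"),
    label = cfg$label,
    morphine_uM = cfg$morphine_uM,
    presyn_mu_or_on = cfg$presyn_mu_or_on,
    postsyn_mu_or_on = cfg$postsyn_mu_or_on,
    astro_mglur_on = cfg$astro_mglur_on,
    gliotransmission_on = cfg$gliotransmission_on,
    glt_factor = cfg$glt_factor
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  df <- as.data.frame(trace)[seq(1, nrow(trace), by = every), , drop = FALSE]
  df[] <- lapply(df, function(col) formatC(col, digits = 17, format = "g"))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param expected_param_hash If non-`NULL`, reading fails when the stored
#'   parameter hash differs (guards against silently mixing traces across
#'   parameter sets).
#' @export
read_trace <- function(path, expected_param_hash = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  if (length(hdr) == 0) stop("not a tripsyn trace file (no metadata header)")
  meta_raw <- sub("^# ", "", lines[hdr])
  keys <- sub(":.*$", "", meta_raw)
  vals <- sub("^[^:]*: ?", "", meta_raw)
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta$format_version) || meta$format_version != "1")
    stop("unsupported trace format version: ",
         meta$format_version %||% "<missing>")
  if (!is.null(expected_param_hash) &&
      !identical(meta$param_hash, expected_param_hash))
    stop("parameter hash mismatch: trace was produced with different constants")
  df <- utils::read.csv(text = lines[-hdr])
  cfg <- scenario_config(
    morphine_uM = as.numeric(meta$morphine_uM),
    presyn_mu_or_on = as.logical(meta$presyn_mu_or_on),
    postsyn_mu_or_on = as.logical(meta$postsyn_mu_or_on),
    astro_mglur_on = as.logical(meta$astro_mglur_on),
    gliotransmission_on = as.logical(meta$gliotransmission_on),
    glt_factor = as.numeric(meta$glt_factor),
    label = meta$label
  )
  attr(df, "config") <- cfg
  attr(df, "dt") <- as.numeric(meta$dt)
  attr(df, "record_dt") <- as.numeric(meta$record_dt)
  attr(df, "seed") <- as.numeric(meta$seed)
  attr(df, "settle_ms") <- as.numeric(meta$settle_ms)
  attr(df, "burn_in_ms") <- as.numeric(meta$burn_in_ms)
  attr(df, "param_hash") <- meta$param_hash
  class(df) <- c("sim_trace", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
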