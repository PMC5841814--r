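# shared short-run cache so independent tests do not re-integrate the same
# scenario; keyed by scenario id / seed / duration / options
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(id, seed = 1, duration_ms = 5000, ...) {
  extra <- list(...)
  key <- paste(id, seed, duration_ms,
               paste(names(extra), unlist(extra), collapse = "_"),
               sep = "|")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- do.call(run_simulation, c(
      list(build_scenario(id), duration_ms = duration_ms, seed = seed),
      extra))
  }
  .run_cache[[key]]
}

# minimal hand-built trace for analysis-level tests
fake_trace <- function(n = 100, glut = 1, glio = 2, ph = 3, gampa = 4) {
  df <- data.frame(t_ms = seq_len(n) * 100, glut_uM = glut, glio_uM = glio,
                   ph_camkii_uM = ph, g_ampa = gampa)
  attr(df, "burn_in_ms") <- 0
  class(df) <- c("sim_trace", "data.frame")
  df
}
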