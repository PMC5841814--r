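#' Monitoring factors of a run
#'
#' The four LTP footprints tracked per scenario — time-averaged cleft
#' glutamate, gliotransmitter, phosphorylated CaMKII and AMPAR conductance —
#' with median, 25-75% and 9-91% quantiles per signal.  Statistics pool the
#' recorded time samples after the burn-in window (the displayed-run
#' convention); means are reported both from the trace samples and, when
#' available, from the engine's full-resolution accumulators.
#'
#' @param trace A `sim_trace`.
#' @param burn_in_ms Samples at or before this time are excluded; defaults
#'   to the trace's own burn-in attribute (5 s).
#' @return A data frame with one row per factor and columns `factor`,
#'   `mean`, `median`, `q09`, `q25`, `q75`, `q91`.
#' @export
monitoring_factors <- function(trace, burn_in_ms = NULL) {
  stopifnot(inherits(trace, "sim_trace"))
  if (is.null(burn_in_ms)) burn_in_ms <- attr(trace, "burn_in_ms") %||% 5000
  keep <- trace$t_ms >= burn_in_ms
  if (!any(keep)) stop("empty analysis window: trace shorter than burn-in")
  cols <- c(glutamate = "glut_uM", gliotransmitter = "glio_uM",
            ph_camkii = "ph_camkii_uM", g_ampa = "g_ampa")
  eng <- attr(trace, "summary")
  eng_means <- c(glutamate = eng$mean_glut %||% NA_real_,
                 gliotransmitter = eng$mean_glio %||% NA_real_,
                 ph_camkii = eng$mean_ph_camkii %||% NA_real_,
                 g_ampa = eng$mean_g_ampa %||% NA_real_)
  out <- lapply(seq_along(cols), function(i) {
    x <- trace[[cols[[i]]]][keep]
    q <- stats::quantile(x, c(0.09, 0.25, 0.5, 0.75, 0.91), names = FALSE)
    m <- eng_means[[i]]
    if (!is.finite(m)) m <- mean(x)
    data.frame(factor = names(cols)[i], mean = m, median = q[3],
               q09 = q[1], q25 = q[2], q75 = q[4], q91 = q[5])
  })
  do.call(rbind, out)
}

#' Run the scenario battery
#'
#' Runs the requested scenarios over one or more seeds, extracts the
#' monitoring factors of every run, and averages them across seeds (with the
#' across-seed coefficient of variation as the dispersion readout).
#'
#' @param ids Scenario ids (subset of 1..13).
#' @param seeds Integer vector of master seeds (>= 1 required).
#' @param morphine_uM Dose for the drug scenarios.
#' @param protocol A [stimulus_protocol()].
#' @param duration_ms Run length (ms).
#' @param dt Step size (ms).
#' @param burn_in_ms Burn-in excluded from the averages (ms).
#' @param params Model parameters.
#' @param keep_traces If `TRUE`, attach the raw traces (memory heavy).
#' @return A `scenario_comparison`: data frame with one row per scenario x
#'   factor, columns `scenario`, `factor`, `mean` (seed-averaged), `cv`
#'   (across seeds), `median`, `q09`, `q25`, `q75`, `q91` (from the first
#'   seed's time-pooled samples), plus failed-run bookkeeping in the
#'   `failures` attribute.
#' @export
scenario_battery <- function(ids = 1:13, seeds = 1:5, morphine_uM = 1,
                             protocol = stimulus_protocol(),
                             duration_ms = 60000, dt = 0.05,
                             burn_in_ms = 5000,
                             params = default_parameters(),
                             keep_traces = FALSE) {
  stopifnot(length(seeds) >= 1, all(ids %in% 1:13))
  rows <- list()
  failures <- list()
  traces <- list()
  for (id in ids) {
    per_seed <- list()
    for (s in seeds) {
      mf <- tryCatch({
        tr <- run_simulation(build_scenario(id, morphine_uM = morphine_uM),
                             protocol = protocol, dt = dt,
                             duration_ms = duration_ms, seed = s,
                             burn_in_ms = burn_in_ms, params = params)
        if (keep_traces) traces[[sprintf("S%d_seed%d", id, s)]] <- tr
        monitoring_factors(tr, burn_in_ms)
      }, error = function(e) e)
      if (inherits(mf, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(scenario = id, seed = s,
                     message = conditionMessage(mf))
      } else {
        per_seed[[length(per_seed) + 1]] <- mf
      }
    }
    if (length(per_seed) == 0) next
    means <- sapply(per_seed, function(m) m$mean)
    mean_avg <- rowMeans(means)
    cv <- apply(means, 1, function(x)
      if (length(x) > 1 && mean(x) != 0) stats::sd(x) / mean(x) else 0)
    first <- per_seed[[1]]
    rows[[length(rows) + 1]] <- data.frame(
      scenario = id, factor = first$factor, mean = mean_avg, cv = cv,
      median = first$median, q09 = first$q09, q25 = first$q25,
      q75 = first$q75, q91 = first$q91
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(failures) > 0)
    do.call(rbind, failures) else NULL
  attr(out, "seeds") <- seeds
  attr(out, "morphine_uM") <- morphine_uM
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

#' Normalize a scenario comparison against a reference scenario
#'
#' Divides every factor by the reference scenario's seed-averaged value,
#' producing the normalized cross-scenario table (the reference row becomes
#' 1 by construction; ratios are invariant under a common rescaling of each
#' factor's units).
#'
#' @param comparison A [scenario_battery()] result.
#' @param reference Scenario id used as denominator (default 13, the normal
#'   condition).
#' @return The comparison with an added `ratio_to_reference` column.
#' @export
normalize_comparison <- function(comparison, reference = 13) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  ref <- comparison[comparison$scenario == reference, c("factor", "mean")]
  if (nrow(ref) == 0) stop("reference scenario ", reference,
                           " not present in comparison")
  if (any(ref$mean == 0)) stop("reference factor mean is zero")
  idx <- match(comparison$factor, ref$factor)
  comparison$ratio_to_reference <- comparison$mean / ref$mean[idx]
  comparison
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("scenario comparison: %d scenario(s), seeds = %s\n",
              length(unique(x$scenario)),
              paste(attr(x, "seeds"), collapse = ",")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  fl <- attr(x, "failures")
  if (!is.null(fl)) {
    cat("failed runs:\n")
    print.data.frame(fl, row.names = FALSE)
  }
  invisible(x)
}

#' Write a battery report
#'
#' Emits `factors.csv` (scenario, factor, mean, median, quantiles, ratio to
#' the normal scenario) and a JSON summary of the normalized ratios.
#'
#' @param comparison A [scenario_battery()] result.
#' @param dir Output directory (created if missing).
#' @param reference Reference scenario id for the ratios.
#' @return The directory, invisibly.
#' @export
write_battery_report <- function(comparison, dir, reference = 13) {
  nc <- normalize_comparison(comparison, reference)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(nc), file.path(dir, "factors.csv"),
                   row.names = FALSE)
  ratios <- split(nc$ratio_to_reference, nc$scenario)
  summary <- lapply(names(ratios), function(sc) {
    stats::setNames(as.list(ratios[[sc]]),
                    nc$factor[nc$scenario == as.numeric(sc)])
  })
  names(summary) <- paste0("S", names(ratios))
  jsonlite::write_json(summary, file.path(dir, "factors_normalized.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
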