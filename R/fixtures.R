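#' Piecewise-constant clamp fixtures
#'
#' Deterministic micro-fixtures for unit tests: a piecewise-constant signal
#' (voltage, calcium or glutamate clamp) on a small time grid, so individual
#' operations can be exercised in milliseconds without running the full
#' model.
#'
#' @param kind One of `"voltage"`, `"calcium"`, `"glutamate"`.
#' @param levels Numeric vector of clamp levels.
#' @param durations Durations (ms) of each level; same length as `levels`.
#' @param dt Grid spacing (ms).
#' @return A `clamp_fixture` list with `kind`, the sample grid `t_ms` and
#'   the clamped `signal`.
#' @examples
#' cl <- make_clamp("calcium", levels = c(0, 50), durations = c(1, 2))
#' range(cl$signal)
#' @export
make_clamp <- function(kind = c("voltage", "calcium", "glutamate"),
                       levels, durations, dt = 0.05) {
  kind <- match.arg(kind)
  if (length(levels) != length(durations))
    stop("levels and durations must have equal length")
  stopifnot(all(durations > 0), dt > 0)
  n_per <- pmax(1L, as.integer(round(durations / dt)))
  signal <- rep(levels, times = n_per)
  structure(list(kind = kind,
                 t_ms = seq_along(signal) * dt - dt,
                 signal = signal),
            class = "clamp_fixture")
}

#' Deterministic mean-field oracle for the release-sensor ladder
#'
#' Solves the 7-state linear master equation of the five-site sensor chain
#' (occupancy probabilities of X, X1..X5, X5*) by dense small-step Euler
#' integration, independent of the stochastic engine.  Used to validate the
#' per-vesicle CTMC: ensemble occupancy means must agree with this solution
#' within Monte-Carlo error.
#'
#' @param c_i Fixed calcium (uM).
#' @param t_end End time (ms).
#' @param dt_fine Oracle step (ms); much finer than the engine step.
#' @param init Initial occupancy distribution (length 7, sums to 1);
#'   defaults to all mass in the empty state X.
#' @param boost NO increment on the association rate.
#' @param params Model parameters.
#' @param sample_every Return every this many oracle steps.
#' @return Data frame with `t_ms` and occupancies `X`, `X1`..`X5`, `X5s`.
#' @export
ladder_oracle <- function(c_i, t_end, dt_fine = 0.002, init = NULL,
                          boost = 0, params = default_parameters(),
                          sample_every = 250) {
  r <- ladder_rates(c_i, boost = boost, params = params)
  if (any(c(r$forward, r$backward) < 0)) stop("negative transition rate")
  if (is.null(init)) init <- c(1, rep(0, 6))
  stopifnot(length(init) == 7, abs(sum(init) - 1) < 1e-12)
  # generator matrix: Q[i, j] = rate i -> j
  Q <- matrix(0, 7, 7)
  for (i in 1:6) Q[i, i + 1] <- r$forward[i]
  for (i in 2:7) Q[i, i - 1] <- r$backward[i - 1]
  diag(Q) <- -rowSums(Q)
  n_steps <- as.integer(round(t_end / dt_fine))
  occ <- init
  out_t <- numeric(0)
  out_occ <- list()
  for (k in 0:n_steps) {
    if (k %% sample_every == 0) {
      out_t <- c(out_t, k * dt_fine)
      out_occ[[length(out_occ) + 1]] <- occ
    }
    if (k == n_steps) break
    occ <- occ + dt_fine * as.vector(occ %*% Q)
  }
  res <- as.data.frame(do.call(rbind, out_occ))
  names(res) <- c("X", paste0("X", 1:5), "X5s")
  cbind(t_ms = out_t, res)
}

#' Stationary distribution of the reversible sensor sub-chain
#'
#' Closed-form equilibrium occupancy of the birth-death part X..X5 at fixed
#' calcium (detailed balance: `pi_k ~ prod_j (fwd_j / bwd_j)`), used as an
#' independent check on long-time oracle behavior.
#'
#' @param c_i Fixed calcium (uM).
#' @param boost NO increment.
#' @param params Model parameters.
#' @return Named numeric vector of equilibrium occupancies of X..X5
#'   (ignoring the irreversible-looking isomerization, which is itself
#'   reversible and included: length 7).
#' @export
ladder_equilibrium <- function(c_i, boost = 0,
                               params = default_parameters()) {
  r <- ladder_rates(c_i, boost = boost, params = params)
  w <- numeric(7)
  w[1] <- 1
  for (i in 1:6) w[i + 1] <- w[i] * r$forward[i] / r$backward[i]
  stats::setNames(w / sum(w), c("X", paste0("X", 1:5), "X5s"))
}

#' List the built-in fixtures
#'
#' @return Character vector of fixture generator names exercised by the test
#'   suite.
#' @export
list_fixtures <- function() {
  c("voltage_clamp_reversal", "calcium_step_halfmax", "glutamate_pulse_train")
}

#' Materialize a named fixture
#'
#' @param name One of [list_fixtures()].
#' @return A `clamp_fixture`.
#' @export
run_fixture <- function(name) {
  switch(name,
    voltage_clamp_reversal =
      make_clamp("voltage", levels = -80, durations = 5),
    calcium_step_halfmax =
      make_clamp("calcium", levels = c(0, 50), durations = c(2, 5)),
    glutamate_pulse_train =
      make_clamp("glutamate", levels = rep(c(0, 100), 5),
                 durations = rep(c(20, 2), 5)),
    stop("unknown fixture: ", name)
  )
}
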