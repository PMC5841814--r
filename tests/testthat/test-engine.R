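test_that("stimulus reproduces the standard pulse train", {
  pr <- stimulus_protocol()
  expect_equal(stimulus(1, pr), 10)
  expect_equal(stimulus(3.9, pr), 10)
  expect_equal(stimulus(4.1, pr), 0)
  expect_equal(stimulus(100, pr), 0)
  expect_equal(stimulus(200.5, pr), 10)    # next period
  # 300 pulses in 60 s at 5 Hz
  t <- seq(0, 60000 - 0.05, by = 0.05)
  on <- stimulus(t, pr) > 0
  expect_equal(sum(diff(c(FALSE, on)) == 1), 300)
  expect_error(stimulus_protocol(width_ms = 300, freq_hz = 5))
})

test_that("scenario registry encodes the thirteen interventions", {
  s13 <- build_scenario(13)
  expect_equal(s13$morphine_uM, 0)
  expect_equal(s13$glt_factor, 1)
  expect_true(s13$presyn_mu_or_on && s13$postsyn_mu_or_on &&
                s13$astro_mglur_on && s13$gliotransmission_on)
  s1 <- build_scenario(1)
  expect_equal(s1$morphine_uM, 1)
  expect_equal(s1$glt_factor, 0.5)
  expect_false(build_scenario(2)$presyn_mu_or_on)
  expect_false(build_scenario(3)$postsyn_mu_or_on)
  s4 <- build_scenario(4)
  expect_false(s4$presyn_mu_or_on || s4$postsyn_mu_or_on)
  expect_false(build_scenario(5)$gliotransmission_on)
  expect_equal(build_scenario(6)$glt_factor, 1.0)
  expect_equal(build_scenario(7)$glt_factor, 1.5)
  expect_false(build_scenario(8)$astro_mglur_on)
  s12 <- build_scenario(12)
  expect_false(s12$postsyn_mu_or_on || s12$astro_mglur_on)
  expect_equal(s12$glt_factor, 1.5)
  expect_error(build_scenario(0))
  expect_error(build_scenario(14))
})

test_that("a fixed seed reproduces the trace bit for bit", {
  a <- run_simulation(build_scenario(1), duration_ms = 3000, seed = 99)
  b <- run_simulation(build_scenario(1), duration_ms = 3000, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- run_simulation(build_scenario(1), duration_ms = 3000, seed = 100)
  expect_false(identical(a$glut_uM, c2$glut_uM))
})

test_that("zero-duration run returns the initial state only", {
  tr <- run_simulation(build_scenario(13), duration_ms = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$t_ms, 0)
})

test_that("too-large steps trigger a stability warning", {
  expect_warning(run_simulation(build_scenario(13), duration_ms = 0,
                                dt = 0.1, settle_ms = 0), "unstable")
})

test_that("trace round-trips losslessly through CSV with metadata", {
  tr <- cached_run(1, duration_ms = 1000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(as.matrix(as.data.frame(back)), as.matrix(as.data.frame(tr)),
               tolerance = 1e-15)
  cfg <- attr(back, "config")
  expect_equal(cfg$label, "S1")
  expect_equal(cfg$glt_factor, 0.5)
  expect_equal(attr(back, "seed"), attr(tr, "seed"))
  expect_equal(attr(back, "param_hash"), attr(tr, "param_hash"))
  # altered parameter provenance is detected
  expect_error(read_trace(path, expected_param_hash = "deadbeef"),
               "hash mismatch")
  # downsample-on-write preserves columns
  write_trace(tr, path, every = 10)
  down <- read_trace(path)
  expect_equal(names(down), names(tr))
  expect_equal(nrow(down), ceiling(nrow(tr) / 10))
})

test_that("postsynaptic flags do not leak into presynaptic columns", {
  pre_cols <- c("v_pre_mV", "v_int_mV", "g_gaba", "i_gabaa_uA_cm2", "mor",
                "cach", "c_fast_uM", "c_slow_uM", "ip3_pre_uM", "glut_uM",
                "R", "E", "release_events", "c_astro_uM", "glio_uM")
  a <- run_simulation(build_scenario(1), duration_ms = 4000, seed = 5,
                      no_feedback = TRUE)
  b <- run_simulation(build_scenario(3), duration_ms = 4000, seed = 5,
                      no_feedback = TRUE)   # postsynaptic muOR off
  for (cc in pre_cols) expect_identical(a[[cc]], b[[cc]])
  # while the postsynaptic side clearly changes
  expect_false(identical(a$mg_unblock, b$mg_unblock))
})

test_that("parameter file round-trip preserves values and units", {
  p <- default_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, path)
  q <- read_parameters(path)
  expect_equal(q$values, p$values)
  expect_equal(q$units, p$units)
  expect_equal(param_hash(q), param_hash(p))
  # a changed value changes the hash; a changed unit tag is rejected
  q$values[["tau_g"]] <- 2
  expect_false(param_hash(q) == param_hash(p))
  q2 <- p
  q2$units[["tau_g"]] <- "s"
  expect_error(validate_parameters(q2), "unit mismatch")
  q3 <- p
  q3$values <- q3$values[-1]
  expect_error(validate_parameters(q3), "missing")
})
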