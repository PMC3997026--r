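test_that("inter-layer weights are pattern-paired and normalised by source size", {
  lex <- generate_lexical_set(c("w1", "w2"), n_units = 500, seed = 1)
  sem <- generate_pattern_set(500, 0.06, semantic_structure(c("c1", "c2")),
                              seed = 2, unrelated_overlap = "zero")
  W <- build_interlayer_weights(lex, sem, c(w1 = "c1", w2 = "c2"),
                                raw_gain = 2)
  expect_identical(sum(W != 0), 2L * 30L * 20L)
  expect_true(all(W[W != 0] == 2 / 20))
  expect_true(all(W >= 0))
  # baseline rows and columns carry no weight
  expect_true(all(W[pattern_units(sem, sem$baseline_id), ] == 0))
  expect_true(all(W[, pattern_units(lex, lex$baseline_id)] == 0))
  expect_error(build_interlayer_weights(lex, sem, c(baseline = "c1"), 2),
               "baseline")
  expect_identical(sum(build_interlayer_weights(lex, sem,
                                                c(w1 = "c1"), 0) != 0), 0L)
})

test_that("external drive rises exponentially to its gain", {
  tau <- 10
  I <- external_drive(1:5, t_since_onset = tau, gain = 1.5, tau_ext = tau,
                      n_units = 20)
  expect_equal(unique(I[1:5]), 1.5 * (1 - exp(-1)))
  expect_true(all(I[6:20] == 0))
  # clear stimuli reach >=99% of gain within 3.3 ms
  I2 <- external_drive(1, 3.3, 0.56, 0.66, 10)
  expect_gt(I2[1], 0.99 * 0.56)
  expect_identical(external_drive(NULL, 50, 1, 1, 10), numeric(10))
})

test_that("assemble_system applies canonical defaults and validates", {
  sys <- vocab_system()
  expect_equal(sys$feedback_gain, 0.21)
  expect_equal(sys$semantic_params$eta_amp, 0.05)   # pronunciation-like
  expect_equal(semantic_layer_params("ldt")$eta_amp, 0.01)
  expect_equal(sys$lexical_params$theta_ext, 0.25)
  expect_equal(sys$coupling$U_between, 0.087)
  expect_equal(sys$coupling$tau_r_between, 1333)
  sys2 <- set_feedback_gain(sys, 0.5145)
  expect_equal(sys2$feedback_gain, 0.5145)
  expect_error(set_feedback_gain(sys, -1), "raw_gain")

  bad_par <- semantic_layer_params()
  bad_par$n_units <- 400L
  expect_error(assemble_system(sys$semantic_set, sys$lexical_set,
                               semantic_params = bad_par), "sizes")
})

test_that("default feedback stays below the lexical threshold; elevated feedback crosses it", {
  sys <- vocab_system()
  # semantic fully on a concept: feedback per paired word unit = gain
  x_sem <- numeric(500); x_sem[pattern_units(sys$semantic_set, "cat")] <- 1
  fb <- 0.21 * as.vector(sys$W_s2l_unit %*% x_sem)
  wu <- pattern_units(sys$lexical_set, "cat")
  expect_equal(unique(round(fb[wu], 10)), 0.21)
  expect_lt(max(fb), sys$lexical_params$theta_ext)       # no influence alone
  expect_gt(0.5145, sys$lexical_params$theta_ext)        # expectancy value crosses
})

test_that("a deterministic resting system does not drift off its baselines", {
  sys <- vocab_system()
  sp <- sys$semantic_params; sp$eta_amp <- 0
  lp <- sys$lexical_params; lp$eta_amp <- 0
  sys0 <- assemble_system(sys$semantic_set, sys$lexical_set,
                          semantic_params = sp, lexical_params = lp)
  st <- system_state(sys0)
  for (i in seq_len(ceiling(300 / sys0$dt)))
    st <- step_system(st, sys0)
  expect_identical(converged_pattern(st$semantic$x, sys0$semantic_set),
                   sys0$semantic_set$baseline_id)
  expect_identical(converged_pattern(st$lexical$x, sys0$lexical_set),
                   sys0$lexical_set$baseline_id)
})

test_that("compiled core and dense R reference integrate identically", {
  sys <- vocab_system()
  sp <- sys$semantic_params; sp$eta_amp <- 0
  lp <- sys$lexical_params; lp$eta_amp <- 0
  sys0 <- assemble_system(sys$semantic_set, sys$lexical_set,
                          semantic_params = sp, lexical_params = lp)
  spec <- trial_spec("dog", "cat", soa = 150, timeout = 600)
  rc <- run_trial(sys0, spec, seed = 1, engine = "cpp")
  rr <- run_trial(sys0, spec, seed = 1, engine = "r")
  expect_equal(rc$rt, rr$rt, tolerance = 1e-9)
  expect_identical(rc$semantic_sequence$id, rr$semantic_sequence$id)
  expect_equal(rc$semantic_sequence$t, rr$semantic_sequence$t, tolerance = 1e-9)
  expect_identical(rc$n_transitions, rr$n_transitions)
})

test_that("bottom-up weights depress during lexical activity, feedback never does", {
  sys <- vocab_system()
  sp <- sys$semantic_params; sp$eta_amp <- 0
  lp <- sys$lexical_params; lp$eta_amp <- 0
  sys0 <- assemble_system(sys$semantic_set, sys$lexical_set,
                          semantic_params = sp, lexical_params = lp)
  st <- system_state(sys0)
  wu <- pattern_units(sys0$lexical_set, "dog")
  # drive the dog word via its visual input for 500 ms
  for (i in seq_len(ceiling(500 / sys0$dt)))
    st <- step_system(st, sys0, lex_stimulus = wu, t_since_onset = i * sys0$dt)
  cu <- pattern_units(sys0$semantic_set, "dog")
  expect_lt(mean(st$W_l2s[cu, wu]), mean(sys0$W_l2s[cu, wu]))
  # depression bounded below by zero, above by the ceiling
  expect_true(all(st$W_l2s >= 0 & st$W_l2s <= sys0$W_l2s + 1e-12))
})

test_that("the orthographic relay delays degraded input and scales with frequency", {
  base <- vocab_system()
  sys <- assemble_system(base$semantic_set, base$lexical_set,
                         orthographic = orthographic_params())
  sp <- trial_spec("dog", "cat", soa = 150)
  clear <- run_trial(sys, sp, seed = 3)
  degr <- run_trial(sys, trial_spec("dog", "cat", soa = 150, degraded = TRUE),
                    seed = 3)
  lowf <- run_trial(sys, trial_spec("dog", "cat", soa = 150, frequency = "low"),
                    seed = 3)
  expect_false(clear$timeout || degr$timeout || lowf$timeout)
  expect_gt(degr$rt, clear$rt)     # degradation slows recognition
  expect_gt(lowf$rt, clear$rt)     # weaker orthographic-to-lexical gain slows it
})
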