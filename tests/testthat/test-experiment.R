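test_that("neutral trials leave both layers on their baselines until the target", {
  sys <- vocab_system()
  sp <- sys$semantic_params; sp$eta_amp <- 0
  lp <- sys$lexical_params; lp$eta_amp <- 0
  sys0 <- assemble_system(sys$semantic_set, sys$lexical_set,
                          semantic_params = sp, lexical_params = lp)
  r <- run_trial(sys0, trial_spec(NA, "cat", soa = 300), seed = 1, record = 20)
  expect_false(r$timeout)
  # no semantic convergence to anything but the baseline before target onset
  pre <- r$semantic_sequence[r$semantic_sequence$t < 300, ]
  expect_identical(nrow(pre), 0L)
  expect_identical(r$n_transitions, 0L)
  # first and only convergence after the target is the target's concept
  expect_identical(r$semantic_sequence$id[1], "cat")
})

test_that("trials are deterministic given a seed", {
  sys <- vocab_system()
  a <- run_trial(sys, trial_spec("dog", "cat", 150), seed = 77)
  b <- run_trial(sys, trial_spec("dog", "cat", 150), seed = 77)
  c <- run_trial(sys, trial_spec("dog", "cat", 150), seed = 78)
  expect_identical(a$rt, b$rt)
  expect_identical(a$semantic_sequence, b$semantic_sequence)
  expect_false(identical(a$rt, c$rt))
})

test_that("low-noise trials never latch", {
  sys <- vocab_system()
  nt <- vapply(1:10, function(s)
    run_trial(sys, trial_spec("dog", "cat", 400), policy = "mode_III",
              seed = 400 + s)$n_transitions, integer(1))
  expect_true(all(nt == 0))
})

test_that("unknown stimuli and timeouts are reported, not thrown", {
  sys <- vocab_system()
  expect_error(run_trial(sys, trial_spec("dog", "no_such_word", 150)),
               "unknown target")
  expect_error(run_trial(sys, trial_spec("no_such_word", "cat", 150)),
               "unknown prime")
  r <- run_trial(sys, trial_spec("dog", "cat", 150, timeout = 5), seed = 1)
  expect_true(r$timeout)
  expect_true(is.na(r$rt))
})

test_that("free association rows are distributions and respect the noise regime", {
  sys <- vocab_system()
  M <- run_free_association(sys, cue_ids = c("dog", "filler8"), n_reps = 20,
                            run_length = 800, seed = 5)
  expect_equal(rowSums(M), c(dog = 1, filler8 = 1))
  expect_true(all(M >= 0))
  # zero noise: free runs never leave the cue
  M0 <- run_free_association(sys, cue_ids = "dog", n_reps = 5, seed = 5,
                             run_length = 500, eta_amp = 0)
  expect_equal(unname(M0[1, "none"]), 1)
})

test_that("stimulus lists realise the requested mix, RP and determinism", {
  pairs <- data.frame(
    prime = c("d1p", "d2p", "d1p", "d2p", "NEUTRAL"),
    target = c("d1t", "d2t", "d2t", "d1t", "d1t"),
    relation = c("related", "related", "unrelated", "unrelated", "neutral"))
  tl <- build_stimulus_list(pairs, 100,
                            mix = c(related = 0.5, unrelated = 0.3,
                                    neutral = 0.2),
                            soa = 150, rp = 0.5, seed = 3)
  expect_length(tl, 100)
  conds <- vapply(tl, `[[`, "", "condition")
  expect_identical(sum(conds == "related"), 50L)
  expect_identical(sum(conds == "neutral"), 20L)
  tl2 <- build_stimulus_list(pairs, 100,
                             mix = c(related = 0.5, unrelated = 0.3,
                                     neutral = 0.2),
                             soa = 150, rp = 0.5, seed = 3)
  expect_identical(tl, tl2)
  expect_error(build_stimulus_list(pairs, 100,
                                   mix = c(related = 0.5, unrelated = 0.5),
                                   soa = 150, rp = 0.2), "inconsistent")
  expect_error(build_stimulus_list(pairs, 10, mix = c(related = 0.7),
                                   soa = 150), "sum to 1")
})

test_that("experiments reset state between trials and record tidy rows", {
  sys <- vocab_system()
  trials <- list(trial_spec("dog", "cat", 150, condition = "related"),
                 trial_spec("filler9", "cat", 150, condition = "unrelated"))
  ex <- run_experiment(sys, trials, seed = 9)
  expect_s3_class(ex, "priming_experiment")
  expect_identical(nrow(ex$records), 2L)
  expect_identical(ex$records$condition, c("related", "unrelated"))
  # full reset: each experiment trial equals the same trial run standalone
  solo <- run_trial(sys, trials[[2]], seed = 9 + 2)
  expect_identical(ex$records$rt[2], solo$rt)
  expect_identical(ex$records$n_transitions[2], solo$n_transitions)
  # determinism of the whole experiment
  ex2 <- run_experiment(sys, trials, seed = 9)
  expect_identical(ex$records, ex2$records)
})
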