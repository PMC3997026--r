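# Shared fixtures, built once per test run. Systems use the canonical
# parameters throughout; pattern-set seeds are fixed so every test sees the
# same realisation.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

vocab_system <- function() fixture("vocab", function() {
  struct <- build_named_structure("mixed_vocab")
  sem <- generate_pattern_set(500, 0.06, struct, seed = 42)
  lex <- generate_lexical_set(pattern_ids(sem, baseline = FALSE), seed = 43)
  assemble_system(sem, lex)
})

ldt_system <- function() fixture("ldt", function() {
  struct <- build_named_structure("mixed_ldt")
  sem <- generate_pattern_set(500, 0.06, struct, seed = 11,
                              baseline_overlap = "zero")
  lex <- generate_lexical_set(pattern_ids(sem, baseline = FALSE), seed = 12)
  assemble_system(sem, lex)
})

freq_system <- function() fixture("freq", function() {
  struct <- build_named_structure("freq_4x4")
  sem <- generate_pattern_set(500, 0.06, struct, seed = 21)
  lex <- generate_lexical_set(pattern_ids(sem, baseline = FALSE), seed = 22)
  assemble_system(sem, lex)
})

# mean RT over seeds for one prime/target cell; NA-safe for timeouts
cell_rts <- function(sys, prime, target, soa, n = 30, policy = "automatic",
                     seed0 = 1000, timeout = 2000, ...) {
  vapply(seq_len(n), function(s) {
    r <- run_trial(sys, trial_spec(prime, target, soa, timeout = timeout, ...),
                   policy = policy, seed = seed0 + s)
    if (r$timeout) NA_real_ else r$rt
  }, numeric(1))
}

# mean RT pooled over several (prime, target) pairs, n seeds per pair
pooled_rts <- function(sys, pairs, soa, n = 25, policy = "automatic",
                       seed0 = 1000, ...) {
  unlist(lapply(seq_len(nrow(pairs)), function(i) {
    cell_rts(sys, pairs$prime[i], pairs$target[i], soa, n = n,
             policy = policy, seed0 = seed0 + 997L * i, ...)
  }))
}

mean_sem <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
}

# Welch-style z for a one-sided "a is faster than b" comparison
rt_diff_z <- function(a, b) {
  ma <- mean_sem(a); mb <- mean_sem(b)
  (mb["mean"] - ma["mean"]) / sqrt(ma["sem"]^2 + mb["sem"]^2)
}
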