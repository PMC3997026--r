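# wrap derived seeds into the 32-bit range R's RNG accepts
wrap_seed <- function(...) {
  as.integer(sum(vapply(list(...), as.numeric, numeric(1))) %% 2147483647)
}

# ---- low-rank factor preparation for the compiled core ----

# J_max = A %*% t(B) - diag(cdiag): Hopfield covariance columns plus one
# rank-1 column pair per episodic link
layer_factors <- function(set, params, dep_variant = "presynaptic") {
  xi <- pattern_matrix(set)
  p <- set$sparseness
  N <- set$n_units
  A <- xi - p
  B <- A / (N * p * (1 - p))
  ep <- set$structure$episodic_links
  if (nrow(ep) > 0) {
    sc <- episodic_scale(set)
    for (i in seq_len(nrow(ep))) {
      A <- cbind(A, ep$kappa[i] * sc * xi[, ep$dest[i]])
      B <- cbind(B, xi[, ep$source[i]])
    }
  }
  list(n_units = N, sparseness = p, gain = params$gain, tau_n = params$tau_n,
       theta = params$theta, lambda = params$lambda,
       theta_ext = params$theta_ext, U = params$U, x_max = params$x_max,
       tau_r = params$tau_r, eta_amp = params$eta_amp,
       tau_corr = params$tau_corr,
       dep_variant = if (dep_variant == "presynaptic") 0L else 1L,
       Xi = xi, A = A, B = B, cdiag = rowSums(A * B),
       baseline = if (is.null(set$baseline_id)) -1L else
         match(set$baseline_id, names(set$units)) - 1L)
}

coupling_factors <- function(system) {
  cp <- system$coupling
  sem <- system$semantic_set
  lex <- system$lexical_set
  pairing <- system$pairing          # word id -> concept id
  n <- length(pairing)
  L2S_U <- matrix(0, sem$n_units, n)
  L2S_V <- matrix(0, lex$n_units, n)
  S2L_U <- matrix(0, lex$n_units, n)
  S2L_V <- matrix(0, sem$n_units, n)
  for (i in seq_len(n)) {
    wu <- pattern_units(lex, names(pairing)[i])
    cu <- pattern_units(sem, pairing[[i]])
    L2S_U[cu, i] <- cp$gain_lex_to_sem / length(wu)
    L2S_V[wu, i] <- 1
    S2L_U[wu, i] <- 1 / length(cu)   # unit gain; scaled at run time
    S2L_V[cu, i] <- 1
  }
  list(L2S_U = L2S_U, L2S_V = L2S_V, S2L_U = S2L_U, S2L_V = S2L_V,
       U_between = cp$U_between, x_max = system$lexical_params$x_max,
       tau_r_between = cp$tau_r_between, ext_gain_lex = cp$ext_gain_lex)
}

# ---- trial specification ----

#' Specify one priming trial
#'
#' @param prime word id of the prime, or `NA`/`"NEUTRAL"` for a neutral trial
#'   (no prime input; both layers rest on their baselines until the target).
#' @param target word id of the target.
#' @param soa prime-to-target stimulus onset asynchrony (ms).
#' @param prime_duration how long the prime input stays on (ms); clipped to
#'   the SOA.
#' @param degraded degraded target (slow visual rise; orthographic variant)?
#' @param frequency target frequency class (orthographic variant).
#' @param timeout give up this long after target onset (ms).
#' @param condition free-form condition label carried into the results.
#' @export
trial_spec <- function(prime, target, soa, prime_duration = 100,
                       degraded = FALSE, frequency = c("high", "low"),
                       timeout = 2000, condition = NA_character_) {
  frequency <- match.arg(frequency)
  if (is.na(prime)) prime <- "NEUTRAL"
  if (timeout <= 0) stop("timeout (measured from target onset) must be > 0")
  prime_duration <- min(prime_duration, soa)
  structure(list(prime = prime, target = target, soa = soa,
                 prime_duration = prime_duration, degraded = degraded,
                 frequency = frequency, timeout = timeout,
                 condition = condition),
            class = "trial_spec")
}

resolve_policy <- function(policy, system) {
  # policy: list(eta = c(pre, post), gain_post = NA) or a shorthand string
  if (is.character(policy)) {
    policy <- switch(policy,
      automatic = list(eta = rep(system$semantic_params$eta_amp, 2),
                       gain_post = NA_real_),
      mode_I = list(eta = c(0.05, 0.05), gain_post = NA_real_),
      mode_II = list(eta = c(0.05, 0.01), gain_post = NA_real_),
      mode_III = list(eta = c(0.01, 0.01), gain_post = NA_real_),
      stop("unknown policy '", policy, "'"))
  }
  if (is.null(policy$gain_post)) policy$gain_post <- NA_real_
  policy
}

#' Run one priming trial
#'
#' Applies the prime input for `prime_duration` ms, switches to the target at
#' the SOA, and integrates until the lexical layer converges on the target
#' word (correlation at or above the convergence threshold) or the timeout
#' expires. On the first latching transition in the semantic layer the noise
#' amplitude switches to its post-transition component and, if the policy
#' carries an elevated feedback gain, the semantic-to-lexical gain switches
#' too. Latching transitions are spontaneous jumps between concept patterns
#' during the prime-target interval; the externally driven departure from
#' the baseline pattern and the post-target convergence do not count.
#'
#' @param system a [assemble_system()] result.
#' @param spec a [trial_spec()].
#' @param policy `"automatic"`, `"mode_I"`, `"mode_II"`, `"mode_III"`, or a
#'   list `list(eta = c(pre, post), gain_post = ...)`.
#' @param seed integer seed for the trial's noise.
#' @param record record correlation trajectories every `record` steps
#'   (0 = off).
#' @param engine `"cpp"` (compiled fast path) or `"r"` (dense reference
#'   integrator; slow, intended for validation).
#' @return a `trial_result`: `rt` (ms from target onset, `NA` on timeout),
#'   `timeout`, `semantic_sequence` (data frame of convergence ids and times),
#'   `n_transitions`, `eta_used`, `gain_final`, and optionally `record`.
#' @export
run_trial <- function(system, spec, policy = "automatic", seed = 1L,
                      record = 0L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(system, "latch_system"), inherits(spec, "trial_spec"))
  policy <- resolve_policy(policy, system)
  lex_ids <- names(system$lexical_set$units)
  target_i <- match(spec$target, lex_ids)
  if (is.na(target_i)) stop("unknown target id '", spec$target, "'")
  prime_i <- if (identical(spec$prime, "NEUTRAL")) -1L else {
    i <- match(spec$prime, lex_ids)
    if (is.na(i)) stop("unknown prime id '", spec$prime, "'")
    i - 1L
  }
  orth <- system$orthographic
  tau_tgt <- if (is.null(orth)) 0.66 else
    if (spec$degraded) orth$tau_ext_degraded else orth$tau_ext_clear
  schedule <- list(prime = prime_i, prime_dur = spec$prime_duration,
                   soa = spec$soa, target = target_i - 1L,
                   timeout = spec$timeout,
                   tau_ext_prime = if (is.null(orth)) 0.66 else orth$tau_ext_clear,
                   tau_ext_target = tau_tgt)
  pol <- list(eta_pre = policy$eta[1], eta_post = policy$eta[2],
              gain = system$feedback_gain, gain_post = policy$gain_post)

  if (engine == "cpp") {
    semf <- layer_factors(system$semantic_set, system$semantic_params)
    lexf <- layer_factors(system$lexical_set, system$lexical_params)
    cpf <- coupling_factors(system)
    orthL <- if (is.null(orth)) list() else
      list(tau_n = orth$tau_n, theta = orth$theta, gain = orth$gain,
           visual_gain = orth$visual_gain,
           gain_lex_to_orth = orth$gain_lex_to_orth,
           gain_orth_to_lex = orth$gain_orth_to_lex[[spec$frequency]])
    out <- .sim_trial_cpp(semf, lexf, cpf, orthL, schedule, pol,
                          system$dt, system$convergence_threshold, 50,
                          as.integer(seed), as.integer(record))
  } else {
    out <- run_trial_r(system, spec, pol, seed)
  }
  sem_ids <- names(system$semantic_set$units)
  res <- list(rt = out$rt, timeout = out$timeout,
              semantic_sequence = data.frame(
                id = sem_ids[out$seq_id + 1L], t = out$seq_t),
              n_transitions = out$n_transitions,
              eta_used = out$eta_used, gain_final = out$gain_final,
              spec = spec, record = out$record)
  class(res) <- "trial_result"
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial", x$spec$prime, "->", x$spec$target,
      "SOA", x$spec$soa, "ms:",
      if (x$timeout) "timeout" else paste0("RT ", round(x$rt, 2), " ms"),
      "|", x$n_transitions, "semantic transition(s)\n")
  invisible(x)
}

# dense reference integrator; used to validate the compiled core
run_trial_r <- function(system, spec, pol, seed) {
  lex_set <- system$lexical_set
  sem_set <- system$semantic_set
  st <- system_state(system)
  st$feedback_gain <- pol$gain
  st$semantic$noise$amplitude <- pol$eta_pre
  lex_ids <- names(lex_set$units)
  target_u <- pattern_units(lex_set, spec$target)
  prime_u <- if (identical(spec$prime, "NEUTRAL")) NULL else
    pattern_units(lex_set, spec$prime)
  dt <- system$dt
  thr <- system$convergence_threshold
  n_steps <- ceiling((spec$soa + spec$timeout) / dt)
  last_conv <- sem_set$baseline_id
  n_trans <- 0L
  first_done <- FALSE
  seq_id <- character()
  seq_t <- numeric()
  rt <- NA_real_
  set.seed(as.integer(seed))
  for (s in seq_len(n_steps) - 1L) {
    t <- s * dt
    if (t >= spec$soa) {
      stim <- target_u; t_on <- t - spec$soa; tau <- 0.66
    } else if (t < spec$prime_duration && !is.null(prime_u)) {
      stim <- prime_u; t_on <- t; tau <- 0.66
    } else {
      stim <- NULL; t_on <- 0; tau <- 0.66
    }
    st <- step_system(st, system, lex_stimulus = stim, t_since_onset = t_on,
                      tau_ext = tau, frequency = spec$frequency, dt = dt)
    cur <- converged_pattern(st$semantic$x, sem_set, thr)
    if (!is.na(cur) && !identical(cur, last_conv)) {
      if (!is.na(last_conv) && !identical(last_conv, sem_set$baseline_id) &&
          (s + 1) * dt < spec$soa) {
        n_trans <- n_trans + 1L
        if (!first_done) {
          first_done <- TRUE
          st$semantic$noise$amplitude <- pol$eta_post
          if (is.finite(pol$gain_post)) st$feedback_gain <- pol$gain_post
        }
      }
      seq_id <- c(seq_id, cur)
      seq_t <- c(seq_t, (s + 1) * dt)
      last_conv <- cur
    } else if (!is.na(cur)) last_conv <- cur
    tnow <- (s + 1) * dt
    if (tnow >= spec$soa &&
        pattern_correlation(st$lexical$x, target_u) >= thr) {
      rt <- tnow - spec$soa
      break
    }
  }
  list(rt = rt, timeout = is.na(rt),
       seq_id = match(seq_id, names(sem_set$units)) - 1L, seq_t = seq_t,
       n_transitions = n_trans,
       eta_used = c(pol$eta_pre, pol$eta_post), gain_final = st$feedback_gain,
       record = NULL)
}

#' Free-association run: first-transition probabilities
#'
#' For each cue, the semantic layer is initialised converged on the cue
#' pattern, receives the cue input for `cue_duration` ms, and then runs
#' freely; the first latching transition (if any) is tallied. This is the
#' model's analogue of a free-association experiment.
#'
#' @param system a `latch_system` (only its semantic layer is used).
#' @param cue_ids concept ids to cue.
#' @param cue_duration cue input duration (ms).
#' @param run_length free-run length (ms).
#' @param n_reps repetitions per cue.
#' @param seed integer seed.
#' @param eta_amp override noise amplitude (default: semantic params).
#' @return matrix of first-transition relative frequencies, one row per cue,
#'   one column per semantic pattern plus a final `none` column; rows sum
#'   to 1.
#' @export
run_free_association <- function(system, cue_ids = NULL, cue_duration = 100,
                                 run_length = 1500, n_reps = 100, seed = 1L,
                                 eta_amp = NULL) {
  stopifnot(n_reps >= 1)
  sem_set <- system$semantic_set
  if (is.null(cue_ids)) cue_ids <- pattern_ids(sem_set, baseline = FALSE)
  params <- system$semantic_params
  if (!is.null(eta_amp)) params$eta_amp <- eta_amp
  semf <- layer_factors(sem_set, params)
  ids <- names(sem_set$units)
  M <- matrix(0, length(cue_ids), length(ids) + 1,
              dimnames = list(cue_ids, c(ids, "none")))
  for (ci in seq_along(cue_ids)) {
    cue <- match(cue_ids[ci], ids) - 1L
    for (r in seq_len(n_reps)) {
      out <- .sim_free_cpp(semf, cue, system$coupling$gain_lex_to_sem,
                           cue_duration, run_length, system$dt,
                           system$convergence_threshold, 50,
                           wrap_seed(seed, 7919 * ci, r))
      dest <- if (length(out$seq_id) > 0) ids[out$seq_id[1] + 1L] else "none"
      M[ci, dest] <- M[ci, dest] + 1
    }
  }
  M / n_reps
}

#' Stationary stability of every stored semantic pattern
#'
#' Initialises the semantic layer converged on each stored pattern in turn
#' and integrates the deterministic dynamics (noise off, depression off) for
#' `duration` ms, reporting the minimum correlation with the pattern over the
#' run. Values near 1 certify that the Hopfield construction made the
#' pattern a genuine fixed point.
#'
#' @param system a `latch_system`.
#' @param duration run length (ms).
#' @return named vector of minimum correlations, one per semantic pattern
#'   (baseline included).
#' @export
pattern_stability <- function(system, duration = 5000) {
  params <- system$semantic_params
  params$eta_amp <- 0
  params$U <- 0
  semf <- layer_factors(system$semantic_set, params)
  ids <- names(system$semantic_set$units)
  vapply(seq_along(ids), function(i) {
    .sim_free_cpp(semf, i - 1L, 0, 0, duration, system$dt,
                  system$convergence_threshold, 50, 1L)$min_cue_corr
  }, numeric(1)) |> stats::setNames(ids)
}

#' Build a randomized stimulus list
#'
#' Realises requested counts of trials per condition and shuffles them,
#' checking the implied relatedness proportion.
#'
#' @param pairs data frame with columns `prime`, `target`, `relation`
#'   (`"related"` counts toward the RP; any other label -- `"unrelated"`,
#'   `"neutral"`, `"mediated"`, `"backward"`, filler types -- does not unless
#'   listed in `related_relations`).
#' @param n_trials total number of trials; drawn from `pairs` by relation in
#'   proportion to `mix`.
#' @param mix named fractions per relation label (must sum to 1).
#' @param soa SOA applied to every trial (ms).
#' @param rp expected relatedness proportion; checked against the realised
#'   list (error if they disagree by more than 1/n_trials).
#' @param related_relations relation labels counted as related.
#' @param seed integer seed for sampling and shuffling.
#' @param ... further arguments passed to [trial_spec()].
#' @return list of [trial_spec()]s.
#' @export
build_stimulus_list <- function(pairs, n_trials, mix, soa, rp = NULL,
                                related_relations = c("related", "direct",
                                                      "mediated", "backward",
                                                      "associative"),
                                seed = 1L, ...) {
  stopifnot(all(c("prime", "target", "relation") %in% names(pairs)))
  if (abs(sum(mix) - 1) > 1e-8) stop("mix fractions must sum to 1")
  counts <- round_half_up(mix * n_trials)
  # fix rounding drift on the largest cell
  counts[which.max(counts)] <- counts[which.max(counts)] +
    n_trials - sum(counts)
  if (any(counts < 0)) stop("infeasible mix")
  if (!is.null(rp)) {
    realized <- sum(counts[names(counts) %in% related_relations]) / n_trials
    if (abs(realized - rp) > 1 / n_trials + 1e-8)
      stop("requested mix realises RP = ", round(realized, 3),
           ", inconsistent with rp = ", rp)
  }
  with_seed(seed, {
    rows <- do.call(rbind, lapply(names(counts), function(rel) {
      n <- counts[[rel]]
      if (n == 0) return(NULL)
      pool <- pairs[pairs$relation == rel, , drop = FALSE]
      if (nrow(pool) == 0) stop("no pairs available for relation '", rel, "'")
      pool[sample.int(nrow(pool), n, replace = n > nrow(pool)), , drop = FALSE]
    }))
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i)
      trial_spec(rows$prime[i], rows$target[i], soa = soa,
                 condition = rows$relation[i], ...))
  })
}

#' Run a whole priming experiment
#'
#' Executes trials sequentially with a full state reset between trials
#' (layers back to their baselines, depression back to the ceiling, noise
#' re-seeded). Under `policy = "reinforcement"` a [control_state()] is
#' threaded across trials: each trial's two noise amplitudes are the learned
#' base values plus exploration noise, and the base values are updated from
#' the reaction-time outcome.
#'
#' @param system a `latch_system`.
#' @param trials list of [trial_spec()]s.
#' @param policy `"automatic"`, `"mode_I"`/`"mode_II"`/`"mode_III"`,
#'   `"reinforcement"`, or a policy list (see [run_trial()]).
#' @param control a [control_state()] for the reinforcement policy.
#' @param expectancy optional [expectancy_policy()]: on the first transition
#'   of each trial the feedback gain switches to its elevated value (and the
#'   noise to the post-transition component).
#' @param seed integer master seed; trial `i` uses `seed + i`.
#' @return a `priming_experiment`: `records` data frame (one row per trial)
#'   plus the final `control` state.
#' @export
run_experiment <- function(system, trials, policy = "automatic",
                           control = control_state(), expectancy = NULL,
                           seed = 1L) {
  reinforce <- identical(policy, "reinforcement")
  gain_post <- if (!is.null(expectancy) && isTRUE(expectancy$enabled))
    expectancy$elevated_gain else NA_real_
  records <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    spec <- trials[[i]]
    if (reinforce) {
      eps <- sample_exploration(control,
                                seed = wrap_seed(as.numeric(seed) * 131, i))
      control$last_epsilon <- eps
      eta <- pmax(control$eta_amp + eps, 0)
      pol <- list(eta = eta, gain_post = gain_post)
    } else {
      pol <- resolve_policy(policy, system)
      if (!is.na(gain_post)) {
        pol$gain_post <- gain_post
        if (isTRUE(expectancy$also_drop_noise) && !is.null(expectancy$eta_post))
          pol$eta[2] <- expectancy$eta_post
      }
      control$last_epsilon <- c(0, 0)
    }
    res <- run_trial(system, spec, policy = pol, seed = wrap_seed(seed, i))
    if (reinforce && !res$timeout) {
      control <- update_noise_amplitudes(control, res$rt)
      control <- update_running_mean(control, res$rt)
    } else if (reinforce) {
      control$n <- control$n + 1L   # timeouts advance the schedule only
    }
    records[[i]] <- data.frame(
      trial = i, prime = spec$prime, target = spec$target,
      condition = spec$condition, soa = spec$soa,
      degraded = spec$degraded, frequency = spec$frequency,
      rt = res$rt, timeout = res$timeout,
      n_transitions = res$n_transitions,
      eta_pre = res$eta_used[1], eta_post = res$eta_used[2],
      gain_final = res$gain_final)
  }
  out <- list(records = do.call(rbind, records), control = control,
              policy = if (is.character(policy)) policy else "custom",
              seed = seed)
  class(out) <- "priming_experiment"
  out
}

#' @export
print.priming_experiment <- function(x, ...) {
  r <- x$records
  cat("Priming experiment:", nrow(r), "trials (policy:", x$policy, ")\n")
  cat("  timeouts:", sum(r$timeout), "; mean RT:",
      round(mean(r$rt[!r$timeout]), 1), "ms\n")
  invisible(x)
}

#' @export
summary.priming_experiment <- function(object, ...) {
  summarize_experiment(object$records, ...)
}
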