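#' Reinforcement-learning controller state
#'
#' The controller tunes the two-component semantic noise amplitude across
#' trials: component 1 is the noise at trial start, component 2 the noise
#' after the first semantic transition. Each trial runs with the base
#' amplitudes plus zero-mean Gaussian exploration whose scale decays over
#' trials; amplitudes are then nudged toward values that beat the running
#' mean reaction time.
#'
#' @param eta_amp initial 2-vector of base amplitudes (trial-start,
#'   post-transition).
#' @param alpha learning rate.
#' @param A exploration scale.
#' @param beta exploration decay rate per trial.
#' @param exploration_scale `"sd"` reads `N(0, A e^{-beta n})` as a standard
#'   deviation (default); `"var"` as a variance.
#' @return object of class `control_state`.
#' @export
control_state <- function(eta_amp = c(0.05, 0.05), alpha = 0.002,
                          A = 0.06, beta = 0.0125,
                          exploration_scale = c("sd", "var")) {
  stopifnot(length(eta_amp) == 2, all(eta_amp >= 0), A >= 0, beta >= 0)
  structure(list(eta_amp = eta_amp, alpha = alpha, A = A, beta = beta,
                 exploration_scale = match.arg(exploration_scale),
                 n = 1L, rt_mean = NA_real_, rt_count = 0L,
                 last_epsilon = c(0, 0)),
            class = "control_state")
}

#' @export
print.control_state <- function(x, ...) {
  cat(sprintf(
    "Controller at trial %d: eta_amp = (%.4f, %.4f), mean RT = %s ms (mode %s)\n",
    x$n, x$eta_amp[1], x$eta_amp[2],
    if (is.na(x$rt_mean)) "-" else sprintf("%.1f", x$rt_mean),
    classify_mode(x$eta_amp)))
  invisible(x)
}

#' Draw the exploration perturbation for the current trial
#'
#' Two independent zero-mean Gaussian draws with scale `A * exp(-beta * n)`
#' (a standard deviation by default), so exploration fades as the experiment
#' progresses.
#'
#' @param state a [control_state()].
#' @param seed optional integer seed.
#' @return numeric 2-vector.
#' @export
sample_exploration <- function(state, seed = NULL) {
  stopifnot(inherits(state, "control_state"), state$n >= 1)
  scale <- state$A * exp(-state$beta * state$n)
  sdv <- if (state$exploration_scale == "sd") scale else sqrt(scale)
  draw <- function() rnorm(2, 0, sdv)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Update the noise amplitudes from a trial outcome
#'
#' `eta(n+1) = eta(n) + alpha * (mean RT of trials 1..n-1 - RT(n)) * eps(n)`,
#' componentwise, clamped at zero. The very first trial performs no update
#' (there is no prior mean); the trial counter always advances.
#'
#' @param state a [control_state()] whose `last_epsilon` was used in the
#'   trial that produced `rt`.
#' @param rt the trial's reaction time (ms); timeouts must be excluded by the
#'   caller.
#' @export
update_noise_amplitudes <- function(state, rt) {
  stopifnot(inherits(state, "control_state"), is.finite(rt))
  if (state$rt_count > 0) {
    state$eta_amp <- pmax(
      state$eta_amp + state$alpha * (state$rt_mean - rt) * state$last_epsilon,
      0)
  }
  state$n <- state$n + 1L
  state
}

#' Update the running mean reaction time
#'
#' Exact incremental mean over all accepted (non-timeout) trials so far.
#'
#' @param state a [control_state()].
#' @param rt accepted reaction time (ms).
#' @export
update_running_mean <- function(state, rt) {
  stopifnot(inherits(state, "control_state"), is.finite(rt))
  state$rt_count <- state$rt_count + 1L
  state$rt_mean <- if (state$rt_count == 1L) rt else
    state$rt_mean + (rt - state$rt_mean) / state$rt_count
  state
}

#' Classify a noise-amplitude vector into a latching mode
#'
#' Mode I: constant high noise, free latching throughout the trial.
#' Mode II: high noise until the first transition, low afterwards (one
#' transition, then hold -- the expectancy-like regime). Mode III: low noise
#' from the start, no transitions.
#'
#' @param eta_amp 2-vector (trial-start, post-transition).
#' @param latch_threshold amplitude above which latching occurs; default
#'   midway between the low (0.01) and high (0.05) canonical settings.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_mode <- function(eta_amp, latch_threshold = 0.03) {
  stopifnot(length(eta_amp) == 2)
  if (eta_amp[1] < latch_threshold) return("III")
  if (eta_amp[2] < latch_threshold) return("II")
  "I"
}

#' Expectancy policy
#'
#' The controlled-expectancy strategy: once the semantic layer has made its
#' first transition within a trial (the "expected" concept is reached), the
#' noise drops to prevent further wandering and the semantic-to-lexical
#' feedback is strengthened so the expected concept pre-activates its word.
#' The gain end-states are taken as given rather than learned online.
#'
#' @param enabled is the policy active?
#' @param elevated_gain raw feedback gain after the first transition
#'   (0.5145 in the category-shift setup, 0.4977 in the
#'   frequency/degradation setup).
#' @param default_gain gain before the first transition.
#' @param also_drop_noise drop the noise to `eta_post` as well?
#' @param eta_post post-transition noise amplitude.
#' @export
expectancy_policy <- function(enabled = TRUE, elevated_gain = 0.5145,
                              default_gain = 0.21, also_drop_noise = TRUE,
                              eta_post = 0.01) {
  if (enabled && elevated_gain < default_gain)
    stop("elevated_gain must be >= default_gain when enabled")
  list(enabled = enabled, elevated_gain = elevated_gain,
       default_gain = default_gain, also_drop_noise = also_drop_noise,
       eta_post = eta_post)
}

#' Apply an expectancy policy to a system after a first-transition event
#'
#' Returns the system with the elevated feedback gain installed (the trial
#' loop restores the default at the next reset). With the policy disabled
#' the system is returned untouched.
#'
#' @param system a `latch_system`.
#' @param policy an [expectancy_policy()].
#' @param event has the first transition occurred?
#' @export
apply_expectancy <- function(system, policy, event = TRUE) {
  if (!isTRUE(policy$enabled) || !isTRUE(event)) return(system)
  set_feedback_gain(system, policy$elevated_gain)
}
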