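#' Layer parameters
#'
#' All parameters governing one attractor layer. Defaults are unset; use
#' [semantic_layer_params()] / [lexical_layer_params()] for the canonical
#' semantic and lexical configurations.
#'
#' @param n_units number of units `N`.
#' @param sparseness pattern sparseness `p`.
#' @param gain neuronal gain `T` of the logistic transfer function.
#' @param tau_n neuronal time constant (ms).
#' @param theta activation threshold (global inhibition).
#' @param lambda regulation coefficient stabilising the mean activity at `p`.
#' @param x_max maximal firing rate (spikes/s); bridges the utilization `U`
#'   (1/spike) and the normalised activity to a 1/ms depression rate.
#' @param theta_ext external-input threshold; afferent input drives the layer
#'   only above it.
#' @param U within-layer synaptic utilization (1/spike); 0 disables depression.
#' @param tau_r synaptic recovery time constant (ms).
#' @param eta_amp noise standard deviation.
#' @param tau_corr noise temporal correlation (ms).
#' @return object of class `layer_params`.
#' @export
layer_params <- function(n_units, sparseness, gain, tau_n, theta, lambda,
                         x_max, theta_ext, U, tau_r, eta_amp, tau_corr) {
  p <- list(n_units = as.integer(n_units), sparseness = sparseness,
            gain = gain, tau_n = tau_n, theta = theta, lambda = lambda,
            x_max = x_max, theta_ext = theta_ext, U = U, tau_r = tau_r,
            eta_amp = eta_amp, tau_corr = tau_corr)
  if (p$gain <= 0) stop("neuronal gain must be > 0")
  if (p$tau_n <= 0 || p$tau_corr <= 0 || p$tau_r <= 0)
    stop("time constants must be > 0")
  if (p$sparseness <= 0 || p$sparseness >= 1) stop("sparseness must be in (0,1)")
  if (p$eta_amp < 0) stop("eta_amp must be >= 0")
  if (p$U < 0) stop("U must be >= 0")
  class(p) <- "layer_params"
  p
}

#' Canonical semantic-layer parameters
#'
#' @param task default semantic noise regime: pronunciation-like tasks start
#'   with high noise (0.05, free latching), lexical-decision-like tasks with
#'   low noise (0.01, transitions suppressed).
#' @param eta_amp override the task-implied noise amplitude.
#' @export
semantic_layer_params <- function(task = c("pronunciation", "ldt"),
                                  eta_amp = NULL) {
  task <- match.arg(task)
  if (is.null(eta_amp)) eta_amp <- if (task == "pronunciation") 0.05 else 0.01
  layer_params(n_units = 500, sparseness = 0.06, gain = 0.05, tau_n = 7,
               theta = 0.02, lambda = 14.75, x_max = 100, theta_ext = 1,
               U = 0.206, tau_r = 93, eta_amp = eta_amp, tau_corr = 17)
}

#' Canonical lexical-layer parameters
#' @export
lexical_layer_params <- function() {
  layer_params(n_units = 500, sparseness = 0.04, gain = 0.05, tau_n = 13,
               theta = 0.17, lambda = 27.75, x_max = 100, theta_ext = 0.25,
               U = 0, tau_r = 93, eta_amp = 0.025, tau_corr = 17)
}

#' @export
print.layer_params <- function(x, ...) {
  cat(sprintf(
    "Layer: N=%d p=%.3g T=%.3g tau_n=%g theta=%.3g lambda=%.4g U=%.3g tau_r=%g eta=%.3g\n",
    x$n_units, x$sparseness, x$gain, x$tau_n, x$theta, x$lambda, x$U,
    x$tau_r, x$eta_amp))
  invisible(x)
}

#' Logistic transfer function
#'
#' `g(z) = 1 / (1 + exp(-z / T))`, mapping local input to activity in (0, 1).
#'
#' @param z local input.
#' @param gain neuronal gain `T` (> 0).
#' @export
logistic <- function(z, gain) {
  if (gain <= 0) stop("neuronal gain must be > 0")
  1 / (1 + exp(-z / gain))
}

logistic_inv <- function(x, gain) gain * log(x / (1 - x))

#' Sparse-pattern Hopfield weight matrix
#'
#' `J_ij = sum_mu (xi_i - p)(xi_j - p) / (N p (1 - p))`, the covariance rule
#' that makes every stored sparse pattern an attractor. The diagonal is set
#' to zero (no self-connections).
#'
#' @param set a `pattern_set`; all patterns including the baseline are stored.
#' @return symmetric `n_units` x `n_units` matrix with zero diagonal.
#' @export
hopfield_weights <- function(set) {
  stopifnot(inherits(set, "pattern_set"))
  xi <- pattern_matrix(set)
  p <- set$sparseness
  N <- set$n_units
  A <- xi - p
  J <- tcrossprod(A) / (N * p * (1 - p))
  diag(J) <- 0
  J
}

#' Add a directed episodic connection between two patterns
#'
#' Adds `kappa * scale` to every weight from an active unit of `source` to an
#' active unit of `dest` (`J[dest_active, source_active] += kappa * scale`),
#' biasing latching transitions from `source` toward `dest` without
#' disturbing other memories.
#'
#' `kappa` is the episodic salience relative to the semantic (Hopfield)
#' connections; when episodic links are installed into a layer's weights the
#' salience is converted into weight units with the same `1/(N p (1-p))`
#' normalisation as the Hopfield rule (`scale = episodic_scale(params)`), so
#' that a salience of order one biases transitions like an extra shared unit
#' rather than overpowering the stored memories. With the default
#' `scale = 1` the raw increment is `kappa` itself.
#'
#' @param J weight matrix.
#' @param source,dest active-unit index vectors (or ids with `set`).
#' @param kappa episodic salience (>= 0); 0.0336 in the canonical setup.
#' @param set optional `pattern_set` to resolve ids.
#' @param scale conversion from salience to weight units.
#' @export
add_episodic_link <- function(J, source, dest, kappa, set = NULL, scale = 1) {
  if (kappa < 0) stop("episodic salience must be >= 0")
  if (!is.null(set)) {
    if (is.character(source)) source <- pattern_units(set, source)
    if (is.character(dest)) dest <- pattern_units(set, dest)
  }
  J[dest, source] <- J[dest, source] + kappa * scale
  diag(J) <- 0
  J
}

#' @rdname add_episodic_link
#' @param params a [layer_params()] (or a `pattern_set`) supplying `N` and `p`.
#' @export
episodic_scale <- function(params) {
  N <- params$n_units
  p <- params$sparseness
  1 / (N * p * (1 - p))
}

#' One Euler step of synaptic depression
#'
#' `dJ_ij/dt = (J_max_ij - J_ij)/tau_r - U * x_max * x_pre * J_ij`, the
#' Tsodyks-Markram depressing-synapse rate equation. Resources are consumed
#' by the presynaptic unit (`variant = "presynaptic"`, the default: `x_pre`
#' is `x[j]` for weight `J[i, j]`); a postsynaptic variant is provided for
#' sensitivity checks.
#'
#' @param J current weights.
#' @param J_max static weight ceiling.
#' @param activity activity vector in `[0, 1]`.
#' @param U utilization (1/spike).
#' @param x_max maximal rate (spikes/s).
#' @param tau_r recovery time constant (ms).
#' @param dt time step (ms).
#' @param variant which unit's activity consumes the resource.
#' @export
step_depression <- function(J, J_max, activity, U, x_max, tau_r, dt,
                            variant = c("presynaptic", "postsynaptic")) {
  variant <- match.arg(variant)
  stopifnot(dt > 0, U >= 0, all(dim(J) == dim(J_max)),
            length(activity) ==
              if (variant == "presynaptic") ncol(J) else nrow(J))
  rate <- U * (x_max / 1000) * activity  # 1/ms
  drive <- if (variant == "presynaptic") {
    sweep(J, 2, rate, `*`)               # columns: presynaptic index j
  } else {
    J * rate                             # rows: postsynaptic index i
  }
  J + dt * ((J_max - J) / tau_r - drive)
}

#' Correlated Gaussian noise process
#'
#' Exact AR(1) discretisation of Gaussian noise with stationary standard
#' deviation `eta_amp` and exponential autocorrelation
#' `f(tau) = eta_amp * exp(-tau / tau_corr)`: retention `exp(-dt/tau_corr)`,
#' innovation sd `eta_amp * sqrt(1 - exp(-2 dt / tau_corr))`. Units are
#' mutually independent.
#'
#' @param n_units number of independent components.
#' @param eta_amp stationary standard deviation.
#' @param tau_corr correlation time (ms).
#' @export
noise_process <- function(n_units, eta_amp, tau_corr) {
  stopifnot(eta_amp >= 0, tau_corr > 0)
  structure(list(n_units = as.integer(n_units), amplitude = eta_amp,
                 tau_corr = tau_corr, state = numeric(n_units)),
            class = "noise_process")
}

#' Advance the noise process one step
#'
#' @param process a [noise_process()].
#' @param dt time step (ms).
#' @return list with `values` (the emitted noise vector) and the updated
#'   `process`.
#' @export
sample_noise <- function(process, dt) {
  stopifnot(inherits(process, "noise_process"), dt > 0)
  rho <- exp(-dt / process$tau_corr)
  innov_sd <- process$amplitude * sqrt(1 - rho^2)
  process$state <- rho * process$state +
    if (innov_sd > 0) rnorm(process$n_units, 0, innov_sd) else 0
  list(values = process$state, process = process)
}

#' Initialise a layer state converged on a pattern
#'
#' Sets `x` to the binary pattern, `h = g^{-1}(clip(x, eps, 1 - eps))`,
#' `J = J_max`, then relaxes the deterministic dynamics (no input, no noise,
#' depression frozen) for `relax` ms so the state sits on the attractor.
#'
#' @param params a [layer_params()].
#' @param J_max static weights.
#' @param on active-unit indices of the pattern to start on (or `NULL` for a
#'   quiescent start at `x = g(-theta/T)`).
#' @param relax relaxation time (ms).
#' @param dt integration step (ms).
#' @return a `layer_state`: list with `h`, `x`, `J`, `J_max`, `noise`
#'   (a [noise_process()]) and `t`.
#' @export
init_layer_state <- function(params, J_max, on = NULL, relax = 50, dt = 0.66) {
  eps <- 1e-6
  N <- params$n_units
  x <- numeric(N)
  if (!is.null(on)) x[on] <- 1
  h <- logistic_inv(pmin(pmax(x, eps), 1 - eps), params$gain)
  st <- list(h = h, x = logistic(h, params$gain), J = J_max, J_max = J_max,
             noise = noise_process(N, params$eta_amp, params$tau_corr),
             t = 0)
  class(st) <- "layer_state"
  if (relax > 0) {
    q <- params
    q$eta_amp <- 0
    st0 <- st
    st0$noise <- noise_process(N, 0, params$tau_corr)
    for (i in seq_len(ceiling(relax / dt)))
      st0 <- step_layer(st0, q, afferent = numeric(N), dt = dt,
                        depress = FALSE)
    st$h <- st0$h
    st$x <- st0$x
  }
  st$t <- 0
  st
}

#' One Euler step of a layer
#'
#' Integrates `tau_n dh/dt = -h + J x - lambda (mean(x) - p) - theta +
#' [I - theta_ext]_+ + eta` and recomputes `x = g(h)`; the recurrent weights
#' undergo synaptic depression.
#'
#' @param state a `layer_state`.
#' @param params a [layer_params()].
#' @param afferent summed external-origin input vector `I` (stimulus plus
#'   inter-layer drive), rectified here once against `theta_ext`.
#' @param dt time step (ms); must satisfy `dt <= tau_n / 4` for stability.
#' @param depress apply synaptic depression this step?
#' @param depression_variant see [step_depression()].
#' @export
step_layer <- function(state, params, afferent, dt,
                       depress = TRUE,
                       depression_variant = "presynaptic") {
  if (dt > params$tau_n / 4)
    stop("dt = ", dt, " too large for tau_n = ", params$tau_n,
         " (need dt <= tau_n / 4)")
  ns <- sample_noise(state$noise, dt)
  state$noise <- ns$process
  rect <- pmax(afferent - params$theta_ext, 0)
  drive <- as.vector(state$J %*% state$x) -
    params$lambda * (mean(state$x) - params$sparseness) -
    params$theta + rect + ns$values
  state$h <- state$h + dt / params$tau_n * (-state$h + drive)
  state$x <- logistic(state$h, params$gain)
  if (depress && params$U > 0) {
    state$J <- step_depression(state$J, state$J_max, state$x, params$U,
                               params$x_max, params$tau_r, dt,
                               variant = depression_variant)
  }
  state$t <- state$t + dt
  state
}

#' Correlation of the layer state with a stored pattern
#'
#' Pearson correlation between the analog activity vector and the binary
#' pattern; reaches 1 only at the pattern itself.
#'
#' @param x activity vector.
#' @param pattern active-unit indices (or id with `set`).
#' @param set optional `pattern_set` to resolve ids.
#' @export
pattern_correlation <- function(x, pattern, set = NULL) {
  if (!is.null(set) && is.character(pattern)) pattern <- pattern_units(set, pattern)
  n <- length(x)
  xi <- numeric(n)
  xi[pattern] <- 1
  if (sd(x) == 0)
    stop("activity vector is constant; correlation undefined")
  cor(x, xi)
}

#' Which stored pattern the state has converged to
#'
#' @param x activity vector.
#' @param set a `pattern_set`.
#' @param threshold convergence threshold on the correlation (0.95 in the
#'   canonical setup).
#' @return the id of the maximally correlated pattern whose correlation
#'   reaches the threshold, or `NA_character_` if none (a constant activity
#'   vector also counts as not converged).
#' @export
converged_pattern <- function(x, set, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (sd(x) == 0) return(NA_character_)
  cors <- vapply(names(set$units),
                 function(id) pattern_correlation(x, set$units[[id]]),
                 numeric(1))
  best <- which.max(cors)  # ties: first in pattern order
  if (cors[best] >= threshold) names(set$units)[best] else NA_character_
}
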