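#' Build inter-layer weights from pattern pairings
#'
#' Every active unit of a source pattern sends an excitatory connection of
#' strength `raw_gain / k_source` to every active unit of the paired target
#' pattern (`k_source` = number of active units in the source pattern, so a
#' fully active source delivers `raw_gain` to each paired target unit).
#' Baseline patterns are never paired and get no inter-layer weights.
#'
#' @param source,target `pattern_set`s of the presynaptic and postsynaptic
#'   layers.
#' @param pairing named character vector mapping source pattern id ->
#'   target pattern id.
#' @param raw_gain raw inter-layer gain before per-pattern normalisation.
#' @return `target$n_units` x `source$n_units` non-negative matrix.
#' @export
build_interlayer_weights <- function(source, target, pairing, raw_gain) {
  stopifnot(inherits(source, "pattern_set"), inherits(target, "pattern_set"))
  if (raw_gain < 0) stop("raw_gain must be >= 0")
  if (!is.null(source$baseline_id) && source$baseline_id %in% names(pairing))
    stop("baseline patterns must not be paired")
  if (!is.null(target$baseline_id) && target$baseline_id %in% pairing)
    stop("baseline patterns must not be paired")
  W <- matrix(0, target$n_units, source$n_units)
  for (sid in names(pairing)) {
    su <- pattern_units(source, sid)
    tu <- pattern_units(target, pairing[[sid]])
    W[tu, su] <- W[tu, su] + raw_gain / length(su)
  }
  W
}

#' External visual drive for a stimulus
#'
#' The input to the active units of the stimulated pattern rises to `gain`
#' with time constant `tau_ext` (`gain * (1 - exp(-t/tau_ext))`): effectively
#' instantaneous for clear stimuli (`tau_ext` = 0.66 ms), slow for degraded
#' ones (134 ms).
#'
#' @param stimulus active-unit indices, or `NULL` for no stimulus (neutral).
#' @param t_since_onset ms since stimulus onset.
#' @param gain maximal input value.
#' @param tau_ext input rise time constant (ms).
#' @param n_units layer size.
#' @return input vector of length `n_units`.
#' @export
external_drive <- function(stimulus, t_since_onset, gain, tau_ext, n_units) {
  I <- numeric(n_units)
  if (is.null(stimulus) || t_since_onset < 0) return(I)
  I[stimulus] <- gain * (1 - exp(-t_since_onset / tau_ext))
  I
}

#' Coupling parameters between the layers
#'
#' @param gain_lex_to_sem raw bottom-up gain (strong, depressing).
#' @param gain_sem_to_lex raw top-down feedback gain; the 0.21 default stays
#'   below the lexical external threshold on its own, the elevated expectancy
#'   values (0.5145, 0.4977) exceed it.
#' @param U_between utilization of the lexical-to-semantic synapses (1/spike);
#'   the feedback synapses never depress.
#' @param tau_r_between recovery time of the depressing inter-layer synapses
#'   (ms); slow, so the bottom-up influence is short-lived.
#' @param ext_gain_lex gain of the direct visual input to the lexical layer.
#' @export
coupling_params <- function(gain_lex_to_sem = 2, gain_sem_to_lex = 0.21,
                            U_between = 0.087, tau_r_between = 1333,
                            ext_gain_lex = 0.56) {
  list(gain_lex_to_sem = gain_lex_to_sem, gain_sem_to_lex = gain_sem_to_lex,
       U_between = U_between, tau_r_between = tau_r_between,
       ext_gain_lex = ext_gain_lex)
}

#' Orthographic relay-layer parameters
#'
#' A layer of per-unit relays between the visual input and the lexical layer
#' (one orthographic unit per lexical unit, no lateral connections), used for
#' frequency and stimulus-degradation simulations. High-frequency words have
#' stronger orthographic-to-lexical connections than low-frequency words;
#' degraded stimuli slow the visual input rise.
#'
#' @param tau_n relay time constant (ms).
#' @param theta relay activation threshold.
#' @param gain relay neuronal gain (near-binary).
#' @param visual_gain gain of the external visual input to the relays.
#' @param gain_lex_to_orth reciprocal lexical-to-orthographic feedback gain.
#' @param gain_orth_to_lex named vector of orthographic-to-lexical gains per
#'   frequency class.
#' @param tau_ext_clear,tau_ext_degraded visual rise time constants (ms).
#' @export
orthographic_params <- function(tau_n = 7, theta = 1.0, gain = 0.01,
                                visual_gain = 1.5,
                                gain_lex_to_orth = 0.75,
                                gain_orth_to_lex = c(high = 0.56, low = 0.543),
                                tau_ext_clear = 0.66,
                                tau_ext_degraded = 134) {
  list(tau_n = tau_n, theta = theta, gain = gain, visual_gain = visual_gain,
       gain_lex_to_orth = gain_lex_to_orth,
       gain_orth_to_lex = gain_orth_to_lex,
       tau_ext_clear = tau_ext_clear, tau_ext_degraded = tau_ext_degraded)
}

#' Assemble the coupled semantic/lexical system
#'
#' Builds the static weights (sparse-Hopfield recurrent matrices with episodic
#' links, pattern-paired inter-layer matrices) and bundles everything the
#' simulation needs. Word and concept patterns are paired one-to-one by the
#' `pairing` map; by default every non-baseline concept id is paired with the
#' identically named word.
#'
#' @param semantic_set,lexical_set `pattern_set`s (with baselines).
#' @param semantic_params,lexical_params [layer_params()].
#' @param coupling [coupling_params()].
#' @param pairing named character vector word id -> concept id; default pairs
#'   identical names.
#' @param orthographic `NULL`, or [orthographic_params()] to insert the relay
#'   layer (the visual input then targets the relays, not the lexical layer).
#' @param dt integration step (ms).
#' @param convergence_threshold correlation threshold for convergence.
#' @return object of class `latch_system`.
#' @export
assemble_system <- function(semantic_set, lexical_set,
                            semantic_params = semantic_layer_params(),
                            lexical_params = lexical_layer_params(),
                            coupling = coupling_params(),
                            pairing = NULL,
                            orthographic = NULL,
                            dt = 0.66,
                            convergence_threshold = 0.95) {
  stopifnot(inherits(semantic_set, "pattern_set"),
            inherits(lexical_set, "pattern_set"))
  if (semantic_set$n_units != semantic_params$n_units ||
      lexical_set$n_units != lexical_params$n_units)
    stop("pattern-set and layer-params sizes disagree")
  if (is.null(pairing)) {
    ids <- intersect(pattern_ids(lexical_set, baseline = FALSE),
                     pattern_ids(semantic_set, baseline = FALSE))
    pairing <- stats::setNames(ids, ids)
  }
  bad <- setdiff(names(pairing), pattern_ids(lexical_set, baseline = FALSE))
  bad <- c(bad, setdiff(unname(pairing), pattern_ids(semantic_set, baseline = FALSE)))
  if (length(bad) > 0)
    stop("pairing refers to unknown or baseline ids: ",
         paste(unique(bad), collapse = ", "))

  J_sem <- hopfield_weights(semantic_set)
  ep <- semantic_set$structure$episodic_links
  if (nrow(ep) > 0) {
    for (i in seq_len(nrow(ep)))
      J_sem <- add_episodic_link(J_sem, ep$source[i], ep$dest[i],
                                 ep$kappa[i], set = semantic_set,
                                 scale = episodic_scale(semantic_set))
  }
  J_lex <- hopfield_weights(lexical_set)
  W_l2s <- build_interlayer_weights(lexical_set, semantic_set, pairing,
                                    coupling$gain_lex_to_sem)
  # stored at unit gain; scaled by the current feedback gain at run time
  W_s2l_unit <- build_interlayer_weights(
    semantic_set, lexical_set,
    stats::setNames(names(pairing), unname(pairing)), 1)

  structure(list(semantic_set = semantic_set, lexical_set = lexical_set,
                 semantic_params = semantic_params,
                 lexical_params = lexical_params,
                 coupling = coupling, pairing = pairing,
                 orthographic = orthographic,
                 J_sem = J_sem, J_lex = J_lex,
                 W_l2s = W_l2s, W_s2l_unit = W_s2l_unit,
                 feedback_gain = coupling$gain_sem_to_lex,
                 dt = dt,
                 convergence_threshold = convergence_threshold),
            class = "latch_system")
}

#' @export
print.latch_system <- function(x, ...) {
  cat("Latching system: semantic", x$semantic_params$n_units, "units /",
      length(x$semantic_set$units), "patterns; lexical",
      x$lexical_params$n_units, "units /", length(x$lexical_set$units),
      "patterns;", if (!is.null(x$orthographic)) "orthographic relay layer;",
      "feedback gain", x$feedback_gain, "\n")
  invisible(x)
}

#' Set the semantic-to-lexical feedback gain
#'
#' Rescales the top-down feedback; effective from the next step, so it can be
#' switched mid-run (the expectancy policy does so after the first semantic
#' transition).
#'
#' @param system a `latch_system` (or a running `system_state`).
#' @param raw_gain new raw gain (>= 0).
#' @export
set_feedback_gain <- function(system, raw_gain) {
  if (raw_gain < 0) stop("raw_gain must be >= 0")
  system$feedback_gain <- raw_gain
  system
}

#' Initialise the runtime state of an assembled system
#'
#' Both layers start converged on their baseline patterns; all depression
#' states start at the ceiling; relay units (if any) start quiescent.
#'
#' @param system a `latch_system`.
#' @param relax per-layer relaxation time (ms), see [init_layer_state()].
#' @return object of class `system_state`.
#' @export
system_state <- function(system, relax = 50) {
  sem <- init_layer_state(system$semantic_params, system$J_sem,
                          on = pattern_units(system$semantic_set,
                                             system$semantic_set$baseline_id),
                          relax = relax, dt = system$dt)
  lex <- init_layer_state(system$lexical_params, system$J_lex,
                          on = pattern_units(system$lexical_set,
                                             system$lexical_set$baseline_id),
                          relax = relax, dt = system$dt)
  st <- list(semantic = sem, lexical = lex,
             W_l2s = system$W_l2s,             # depressing copy
             feedback_gain = system$feedback_gain,
             orth = NULL, t = 0)
  if (!is.null(system$orthographic)) {
    n <- system$lexical_params$n_units
    h <- rep(-system$orthographic$theta, n)
    st$orth <- list(h = h, x = logistic(h, system$orthographic$gain))
  }
  class(st) <- "system_state"
  st
}

#' One Euler step of the coupled system (reference path)
#'
#' Each layer's external-origin inputs (visual or orthographic drive plus
#' inter-layer drive) are summed and rectified once against that layer's
#' external threshold inside [step_layer()]. This is the plain-R reference
#' integrator; [run_trial()] uses the compiled core, which is algebraically
#' identical.
#'
#' @param state a [system_state()].
#' @param system the `latch_system`.
#' @param lex_stimulus active lexical (word) units currently stimulated, or
#'   `NULL`.
#' @param t_since_onset ms since onset of that stimulus.
#' @param tau_ext visual input rise time (ms).
#' @param frequency frequency class (orthographic variant only).
#' @param dt time step (ms).
#' @export
step_system <- function(state, system, lex_stimulus = NULL,
                        t_since_onset = 0, tau_ext = 0.66,
                        frequency = "high", dt = system$dt) {
  cp <- system$coupling
  orth <- system$orthographic
  x_lex <- state$lexical$x
  x_sem <- state$semantic$x

  # bottom-up drive through depressing lexical-to-semantic weights
  aff_sem <- as.vector(state$W_l2s %*% x_lex)
  # top-down feedback (never depressed), scaled by the current gain
  fb <- state$feedback_gain * as.vector(system$W_s2l_unit %*% x_sem)

  if (is.null(orth)) {
    vis <- external_drive(lex_stimulus, t_since_onset, cp$ext_gain_lex,
                          tau_ext, system$lexical_params$n_units)
    aff_lex <- vis + fb
  } else {
    vis <- external_drive(lex_stimulus, t_since_onset, orth$visual_gain,
                          tau_ext, system$lexical_params$n_units)
    g_o2l <- orth$gain_orth_to_lex[[frequency]]
    aff_lex <- g_o2l * state$orth$x + fb
    # relay units: same h-equation without recurrent or regulation terms
    drive_o <- vis + orth$gain_lex_to_orth * x_lex - orth$theta
    state$orth$h <- state$orth$h + dt / orth$tau_n * (-state$orth$h + drive_o)
    state$orth$x <- logistic(state$orth$h, orth$gain)
  }

  state$semantic <- step_layer(state$semantic, system$semantic_params,
                               afferent = aff_sem, dt = dt)
  state$lexical <- step_layer(state$lexical, system$lexical_params,
                              afferent = aff_lex, dt = dt)
  # inter-layer depression, driven by the presynaptic (lexical) activity
  state$W_l2s <- step_depression(state$W_l2s, system$W_l2s, x_lex,
                                 cp$U_between, system$lexical_params$x_max,
                                 cp$tau_r_between, dt)
  state$t <- state$t + dt
  state
}
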