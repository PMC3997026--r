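# default configuration blocks, keyed by the canonical parameter names
default_config <- function() {
  list(
    dt = 0.66,
    convergence_threshold = 0.95,
    semantic = list(n_units = 500, sparseness = 0.06, gain = 0.05, tau_n = 7,
                    theta = 0.02, lambda = 14.75, x_max = 100, theta_ext = 1,
                    U = 0.206, tau_r = 93, eta_amp = 0.05, tau_corr = 17),
    lexical = list(n_units = 500, sparseness = 0.04, gain = 0.05, tau_n = 13,
                   theta = 0.17, lambda = 27.75, x_max = 100,
                   theta_ext = 0.25, U = 0, tau_r = 93, eta_amp = 0.025,
                   tau_corr = 17),
    coupling = list(gain_lex_to_sem = 2, gain_sem_to_lex = 0.21,
                    U_between = 0.087, tau_r_between = 1333,
                    ext_gain_lex = 0.56),
    task = list(type = "pronunciation_like", seed = 1L),
    experiment = list()
  )
}

merge_defaults <- function(given, defaults, path = "") {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s) ", paste0(path, unknown, collapse = ", "))
  for (k in names(defaults)) {
    if (is.null(given[[k]])) {
      given[k] <- list(defaults[[k]])
    } else if (is.list(defaults[[k]])) {
      if (!is.list(given[[k]]))
        stop("config block '", path, k, "' must be a mapping")
      given[[k]] <- merge_defaults(given[[k]], defaults[[k]],
                                   paste0(path, k, "."))
    }
  }
  given
}

#' Parse and validate a simulation configuration
#'
#' Reads a YAML (or already-parsed list) configuration with blocks
#' `semantic`, `lexical`, `coupling`, `task`, `experiment` plus top-level
#' `dt` and `convergence_threshold`. Missing keys are filled with the
#' canonical defaults; unknown keys are rejected with a descriptive error.
#'
#' @param x path to a YAML file, a YAML string, or a list.
#' @return validated configuration list of class `latch_config`.
#' @export
parse_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (length(x) == 1 && file.exists(x)) yaml::read_yaml(x)
    else yaml::yaml.load(paste(x, collapse = "\n"))
  } else if (is.list(x)) x
  else stop("config must be a file path, YAML text or a list")
  if (is.null(cfg)) cfg <- list()
  for (block in c("semantic", "lexical", "coupling", "experiment"))
    if (block %in% names(cfg) && is.null(cfg[[block]]))
      stop("config block '", block, "' is present but empty")
  cfg <- merge_defaults(cfg, default_config())
  if (cfg$dt <= 0) stop("dt must be > 0")
  if (!is.list(cfg$experiment))
    stop("config block 'experiment' must be a mapping")
  # instantiating the layer params enforces the remaining invariants
  cfg$semantic_params <- do.call(layer_params, cfg$semantic)
  cfg$lexical_params <- do.call(layer_params, cfg$lexical)
  class(cfg) <- c("latch_config", "list")
  cfg
}

#' Serialise a configuration to YAML
#'
#' `parse_config(serialize_config(cfg))` round-trips.
#'
#' @param cfg a [parse_config()] result.
#' @param path optional file to write.
#' @export
serialize_config <- function(cfg, path = NULL) {
  drop <- c("semantic_params", "lexical_params")
  out <- unclass(cfg)[setdiff(names(cfg), drop)]
  txt <- yaml::as.yaml(out)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

# registry of derived streams lives per derive_rng() "registry" environment
#' Derive an independent seeded RNG stream
#'
#' Maps (master seed, stream label) deterministically to a child seed, so
#' e.g. pattern generation, noise, exploration and list shuffling consume
#' independent streams and adding trials never perturbs pattern generation.
#' Registering the same label twice in one registry errors.
#'
#' @param master_seed integer master seed.
#' @param label unique consumer label.
#' @param registry optional environment tracking labels ([new_rng_registry()]).
#' @return integer child seed in `[0, 2^31)`.
#' @export
derive_rng <- function(master_seed, label, registry = NULL) {
  if (!is.null(registry)) {
    if (!is.null(registry[[label]]))
      stop("stream label '", label, "' already registered")
    registry[[label]] <- TRUE
  }
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 2654435761) %% 2147483647)
}

#' @rdname derive_rng
#' @export
new_rng_registry <- function() new.env(parent = emptyenv())

#' Write per-trial records to CSV with a provenance header
#'
#' @param records data frame (e.g. `run_experiment()$records`).
#' @param path output file.
#' @param seed master seed to record in the header.
#' @export
write_records_csv <- function(records, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# semlatch ",
                      as.character(utils::packageVersion("semlatch"))),
               paste0("# seed: ", seed)), con)
  write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read records written by [write_records_csv()]
#' @param path CSV file.
#' @export
read_records_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Serialise a semantic structure to YAML
#'
#' @param structure a [semantic_structure()].
#' @param path optional output file.
#' @export
write_structure <- function(structure, path = NULL) {
  out <- list(pattern_ids = structure$pattern_ids,
              overlap_class = lapply(seq_len(nrow(structure$overlap_class)),
                                     function(i) as.list(structure$overlap_class[i, ])),
              episodic_links = lapply(seq_len(nrow(structure$episodic_links)),
                                      function(i) as.list(structure$episodic_links[i, ])),
              fractions = as.list(structure$fractions))
  txt <- yaml::as.yaml(out)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Read a semantic structure from YAML
#' @param x path or YAML text.
#' @export
read_structure <- function(x) {
  y <- if (length(x) == 1 && file.exists(x)) yaml::read_yaml(x)
  else yaml::yaml.load(paste(x, collapse = "\n"))
  oc <- if (length(y$overlap_class) > 0)
    do.call(rbind, lapply(y$overlap_class, as.data.frame)) else NULL
  ep <- if (length(y$episodic_links) > 0)
    do.call(rbind, lapply(y$episodic_links, as.data.frame)) else NULL
  semantic_structure(unlist(y$pattern_ids), oc, ep,
                     fractions = unlist(y$fractions))
}

#' Write a pattern set as a plain-text unit listing
#'
#' One row per (pattern, unit) for reproducibility and inspection.
#'
#' @param set a `pattern_set`.
#' @param path CSV file.
#' @export
write_pattern_set <- function(set, path) {
  df <- do.call(rbind, lapply(names(set$units), function(id)
    data.frame(id = id, unit = set$units[[id]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# n_units: ", set$n_units),
               paste0("# sparseness: ", set$sparseness),
               paste0("# baseline: ", set$baseline_id)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pattern set written by [write_pattern_set()]
#' @param path CSV file.
#' @export
read_pattern_set <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- function(key) sub(paste0("# ", key, ": "), "", hdr[grepl(key, hdr)])
  df <- read.csv(path, comment.char = "#")
  ids <- unique(df$id)
  baseline <- meta("baseline")
  structure(list(n_units = as.integer(meta("n_units")),
                 sparseness = as.numeric(meta("sparseness")),
                 units = stats::setNames(
                   lapply(ids, function(i) sort(df$unit[df$id == i])), ids),
                 baseline_id = if (baseline == "NULL") NULL else baseline,
                 structure = semantic_structure(setdiff(ids, baseline))),
            class = "pattern_set")
}
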