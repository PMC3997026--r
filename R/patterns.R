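#' @useDynLib semlatch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif sd median
#' @importFrom utils head read.csv write.csv
NULL

# round-half-up; base round() is round-half-even which would give the wrong
# shared-unit counts for e.g. 0.5-valued products
round_half_up <- function(x) floor(x + 0.5)

# sample() semantics without the scalar-x surprise
sample_from <- function(x, n = length(x)) x[sample.int(length(x), n)]

# Run code under a temporary seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Overlap-class fractions
#'
#' Fraction of a pattern's active units shared by a correlated pair, per
#' relatedness class. Strong pairs share 10% of their active units, moderate
#' 6.6%, weak 3.3%. `none` marks an undesignated pair (no shared units, or
#' chance-level sharing under the `"chance"` generation mode); `zero` marks a
#' verified-unrelated pair that shares no units even in `"chance"` mode —
#' the construction-level analogue of stimulus pairs whose unrelatedness was
#' explicitly normed, used for the evaluation crossings of the built-in
#' experiment lists.
#' @export
class_fractions <- c(strong = 0.10, moderate = 0.066, weak = 0.033,
                     none = 0, zero = 0)

#' Describe a semantic structure
#'
#' A semantic structure lists the concept labels, the pairwise overlap classes
#' that encode graded semantic relatedness, and directed episodic links that
#' bias latching transitions between specific concepts.
#'
#' @param pattern_ids character vector of concept labels.
#' @param overlap_class data frame with columns `a`, `b`, `class`
#'   (`"strong"`, `"moderate"` or `"weak"`); pairs not listed are unrelated.
#'   The relation is symmetric; each unordered pair may appear once.
#' @param episodic_links data frame with columns `source`, `dest`, `kappa`
#'   (directed), or `NULL`.
#' @param fractions named fractions of shared active units per class.
#' @return an object of class `semantic_structure`.
#' @export
semantic_structure <- function(pattern_ids,
                               overlap_class = NULL,
                               episodic_links = NULL,
                               fractions = class_fractions) {
  stopifnot(is.character(pattern_ids), !anyDuplicated(pattern_ids))
  if (is.null(overlap_class)) {
    overlap_class <- data.frame(a = character(), b = character(),
                                class = character())
  }
  overlap_class <- as.data.frame(overlap_class)
  stopifnot(all(c("a", "b", "class") %in% names(overlap_class)))
  bad <- setdiff(c(overlap_class$a, overlap_class$b), pattern_ids)
  if (length(bad) > 0)
    stop("overlap_class refers to unknown ids: ", paste(bad, collapse = ", "))
  if (!all(overlap_class$class %in% names(fractions)))
    stop("unknown overlap class; expected one of ",
         paste(names(fractions), collapse = ", "))
  if (any(overlap_class$a == overlap_class$b))
    stop("overlap_class must not pair a pattern with itself")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key(overlap_class$a, overlap_class$b)))
    stop("each unordered pair may appear at most once in overlap_class")
  if (!is.null(episodic_links)) {
    episodic_links <- as.data.frame(episodic_links)
    stopifnot(all(c("source", "dest", "kappa") %in% names(episodic_links)))
    bad <- setdiff(c(episodic_links$source, episodic_links$dest), pattern_ids)
    if (length(bad) > 0)
      stop("episodic_links refer to unknown ids: ", paste(bad, collapse = ", "))
    if (any(episodic_links$kappa < 0)) stop("episodic salience must be >= 0")
  } else {
    episodic_links <- data.frame(source = character(), dest = character(),
                                 kappa = numeric())
  }
  if (any(fractions < 0) || any(fractions > 1))
    stop("class fractions must lie in [0, 1]")
  structure(list(pattern_ids = pattern_ids,
                 overlap_class = overlap_class,
                 episodic_links = episodic_links,
                 fractions = fractions),
            class = "semantic_structure")
}

#' @export
print.semantic_structure <- function(x, ...) {
  cat("Semantic structure:", length(x$pattern_ids), "patterns,",
      nrow(x$overlap_class), "correlated pairs,",
      nrow(x$episodic_links), "episodic links\n")
  invisible(x)
}

# symmetric lookup of the overlap class of a pair; "none" when unlisted
overlap_class_of <- function(structure, a, b) {
  oc <- structure$overlap_class
  hit <- (oc$a == a & oc$b == b) | (oc$a == b & oc$b == a)
  if (any(hit)) oc$class[which(hit)[1]] else "none"
}

# required shared-unit count for a pair given pattern size k
required_overlap <- function(structure, a, b, k) {
  round_half_up(structure$fractions[[overlap_class_of(structure, a, b)]] * k)
}

#' Generate a sparse binary pattern set with prescribed pairwise overlaps
#'
#' Patterns are subsets of `round(p * n_units)` unit indices. Each correlated
#' pair shares exactly `round(fraction * pattern_size)` units. Pairs of class
#' `"none"` are handled per `unrelated_overlap`:
#' \describe{
#'   \item{`"chance"` (default)}{unrelated patterns are drawn with chance-level
#'     overlaps (correlation near zero, as in random sparse patterns), capped
#'     at `chance_cap` shared units. This is the semantic-layer default: with
#'     the covariance Hopfield rule, strictly disjoint unrelated patterns
#'     systematically weaken cross-pattern inhibition (every unit falls in at
#'     most one pattern, leaving a `+p^2` background per stored pattern) and
#'     correlated neighbours are then statically recruited into mixture
#'     states; chance-level reuse of units restores the random-pattern
#'     statistics the rule is built for, and the cap removes the chance tail
#'     that would otherwise seed partial mixtures.}
#'   \item{`"zero"`}{unrelated pairs share no units at all (dedicated block
#'     allocation, each unit in at most one pattern or one pair block). Used
#'     for lexical sets, where all word patterns are strictly disjoint.}
#' }
#' A baseline pattern is appended: it is the attractor both networks rest on
#' at trial start and the stand-in for a neutral prime. It is never paired
#' across layers; within the layer it is uncorrelated with every stored
#' pattern at the same level as any unrelated pair (chance-level shared units
#' in `"chance"` mode, none in `"zero"` mode), so neutral primes seed the
#' upcoming target exactly as much as an unrelated prime word does.
#'
#' @param n_units number of units in the layer.
#' @param sparseness fraction `p` of active units per pattern.
#' @param structure a [semantic_structure()]; use one with no correlated pairs
#'   for a lexical (mutually disjoint) set.
#' @param seed integer seed; the same seed and structure give an identical set.
#' @param baseline_id label for the appended baseline pattern, or `NULL` to
#'   omit it.
#' @param unrelated_overlap `"chance"` or `"zero"`, see above.
#' @param chance_cap maximum shared units between unrelated patterns in
#'   `"chance"` mode.
#' @param baseline_overlap `"chance"` gives the baseline the same
#'   chance-level sharing as any unrelated pattern; `"zero"` makes it
#'   strictly disjoint, appropriate when the stored patterns designate their
#'   evaluation crossings as `zero`-class so that neutral and unrelated
#'   primes are symmetric by construction.
#' @return an object of class `pattern_set`: list with `n_units`,
#'   `sparseness`, `units` (named list of sorted unit indices, 1-based),
#'   `baseline_id`, and the originating `structure`.
#' @export
generate_pattern_set <- function(n_units, sparseness, structure,
                                 seed = 1L, baseline_id = "baseline",
                                 unrelated_overlap = c("chance", "zero"),
                                 chance_cap = 2L,
                                 baseline_overlap = unrelated_overlap) {
  unrelated_overlap <- match.arg(unrelated_overlap)
  baseline_overlap <- match.arg(baseline_overlap, c("chance", "zero"))
  stopifnot(inherits(structure, "semantic_structure"),
            n_units >= 1, sparseness > 0, sparseness < 1)
  ids <- structure$pattern_ids
  if (!is.null(baseline_id) && baseline_id %in% ids)
    stop("baseline_id collides with a pattern id")
  k <- round_half_up(sparseness * n_units)
  npat <- length(ids)

  # overlap demands per unordered pair (deterministic order)
  pairs <- if (npat >= 2) t(utils::combn(ids, 2)) else
    matrix(character(), ncol = 2)
  odem <- if (nrow(pairs) > 0)
    vapply(seq_len(nrow(pairs)),
           function(i) required_overlap(structure, pairs[i, 1], pairs[i, 2], k),
           numeric(1))
  else numeric(0)

  per_pattern_shared <- vapply(ids, function(id) {
    sum(odem[pairs[, 1] == id | pairs[, 2] == id])
  }, numeric(1))
  if (any(per_pattern_shared > k))
    stop("infeasible overlap demands: pattern '",
         ids[which.max(per_pattern_shared)],
         "' would need ", max(per_pattern_shared),
         " shared units but has only ", k)
  if (unrelated_overlap == "zero") {
    n_distinct <- npat * k - sum(odem) +
      if (is.null(baseline_id)) 0 else k
    if (n_distinct > n_units)
      stop("infeasible overlap demands: ", n_distinct,
           " distinct units required but the layer has only ", n_units)
  }

  with_seed(seed, {
    chance_baseline <- baseline_overlap == "chance" && !is.null(baseline_id)
    units <- if (unrelated_overlap == "zero")
      allocate_disjoint(ids, pairs, odem, k, n_units)
    else
      allocate_chance(c(ids, if (chance_baseline) baseline_id),
                      structure, k, n_units, chance_cap)
    if (!is.null(baseline_id) && !chance_baseline) {
      free <- setdiff(seq_len(n_units), unique(unlist(units)))
      if (length(free) < k)
        stop("cannot place a disjoint baseline: ", length(free),
             " unused units remain but ", k, " are needed")
      units[[baseline_id]] <- sort(sample_from(free, k))
    }
    structure(list(n_units = n_units, sparseness = sparseness,
                   units = units, baseline_id = baseline_id,
                   structure = structure),
              class = "pattern_set")
  })
}

# dedicated shared block per correlated pair; every other unit used once
allocate_disjoint <- function(ids, pairs, odem, k, n_units) {
  pool <- sample.int(n_units)
  take <- function(n) {
    if (n > length(pool)) stop("unit pool exhausted")
    u <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    u
  }
  units <- stats::setNames(rep(list(integer()), length(ids)), ids)
  for (i in seq_along(odem)) {
    if (odem[i] == 0) next
    block <- take(odem[i])
    units[[pairs[i, 1]]] <- c(units[[pairs[i, 1]]], block)
    units[[pairs[i, 2]]] <- c(units[[pairs[i, 2]]], block)
  }
  for (id in ids)
    units[[id]] <- sort(c(units[[id]], take(k - length(units[[id]]))))
  units
}

# sequential random allocation: exact shared counts with designated
# neighbours, chance-level (capped) overlap with everything else
allocate_chance <- function(ids, structure, k, n_units, cap) {
  units <- list()
  for (id in ids) {
    nbs <- Filter(function(m) overlap_class_of(structure, id, m) != "none",
                  names(units))
    nb_units <- unlist(units[nbs], use.names = FALSE)
    forced <- integer()
    for (m in nbs) {
      o <- required_overlap(structure, id, m, k)
      if (o == 0) next
      # candidates: this neighbour's units that belong to no other designated
      # neighbour (keeps every designated count exact)
      cand <- setdiff(units[[m]],
                      c(forced, unlist(units[setdiff(nbs, m)],
                                       use.names = FALSE)))
      if (length(cand) < o)
        stop("cannot realise the designated overlap between '", id,
             "' and '", m, "'")
      forced <- c(forced, sample_from(cand, o))
    }
    chosen <- forced
    others <- setdiff(names(units), nbs)
    share <- vapply(units[others],
                    function(v) length(intersect(chosen, v)), numeric(1))
    pool <- sample_from(setdiff(seq_len(n_units), union(chosen, nb_units)))
    pi <- 1
    while (length(chosen) < k) {
      if (pi > length(pool))
        stop("unit pool exhausted while generating pattern '", id, "'")
      u <- pool[pi]
      pi <- pi + 1
      inpat <- others[vapply(units[others], function(v) u %in% v, logical(1))]
      if (length(inpat) == 0 || all(share[inpat] < cap)) {
        chosen <- c(chosen, u)
        share[inpat] <- share[inpat] + 1
      }
    }
    units[[id]] <- sort(chosen)
  }
  units
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set:", length(x$units), "patterns of",
      round_half_up(x$sparseness * x$n_units), "active units in",
      x$n_units, "units",
      if (!is.null(x$baseline_id)) paste0("(incl. baseline '", x$baseline_id, "')"),
      "\n")
  invisible(x)
}

#' Count shared active units of two patterns
#'
#' @param a,b integer vectors of active-unit indices, or pattern ids resolved
#'   in `set`.
#' @param set optional [generate_pattern_set()] result used to resolve ids.
#' @return number of shared active units (symmetric).
#' @export
overlap_count <- function(a, b, set = NULL) {
  if (!is.null(set)) {
    if (is.character(a)) a <- pattern_units(set, a)
    if (is.character(b)) b <- pattern_units(set, b)
  }
  length(intersect(a, b))
}

#' Active units of a named pattern
#' @param set a `pattern_set`.
#' @param id pattern label.
#' @export
pattern_units <- function(set, id) {
  u <- set$units[[id]]
  if (is.null(u)) stop("unknown pattern id '", id, "'")
  u
}

#' All pattern ids of a set (baseline last)
#' @param set a `pattern_set`.
#' @param baseline include the baseline pattern?
#' @export
pattern_ids <- function(set, baseline = TRUE) {
  ids <- names(set$units)
  if (!baseline && !is.null(set$baseline_id)) ids <- setdiff(ids, set$baseline_id)
  ids
}

#' Binary pattern matrix
#'
#' @param set a `pattern_set`.
#' @return 0/1 matrix, `n_units` rows by one column per pattern (baseline
#'   included, in `names(set$units)` order).
#' @export
pattern_matrix <- function(set) {
  m <- matrix(0, set$n_units, length(set$units),
              dimnames = list(NULL, names(set$units)))
  for (id in names(set$units)) m[set$units[[id]], id] <- 1
  m
}

#' Draw a pattern disjoint from an existing set
#'
#' @param existing a `pattern_set`.
#' @param seed integer seed.
#' @param id label for the new pattern.
#' @return the `pattern_set` with the new zero-overlap pattern appended.
#' @export
make_baseline_pattern <- function(existing, seed = 1L, id = "baseline") {
  stopifnot(inherits(existing, "pattern_set"))
  if (id %in% names(existing$units)) stop("id '", id, "' already present")
  k <- round_half_up(existing$sparseness * existing$n_units)
  used <- sort(unique(unlist(existing$units)))
  free <- setdiff(seq_len(existing$n_units), used)
  if (length(free) < k)
    stop("cannot build a disjoint pattern: ", length(free),
         " unused units remain but ", k, " are needed")
  with_seed(seed, {
    existing$units[[id]] <- sort(sample_from(free, k))
  })
  if (is.null(existing$baseline_id)) existing$baseline_id <- id
  existing
}

neighbourhood_structure <- function(prefix_words, within_class = "moderate",
                                    episodic = NULL) {
  ids <- unlist(prefix_words)
  oc <- do.call(rbind, lapply(prefix_words, function(w) {
    if (length(w) < 2) return(NULL)
    p <- t(utils::combn(w, 2))
    data.frame(a = p[, 1], b = p[, 2], class = within_class)
  }))
  semantic_structure(ids, oc, episodic)
}

#' Built-in semantic structures
#'
#' Canonical 16-concept structures used in the simulated experiments:
#' \describe{
#'   \item{`mixed_vocab`}{A small mixed vocabulary (dog, cat, kitten, mouse,
#'     beware plus uncorrelated fillers) with graded correlations and directed
#'     episodic links: dog and cat are strongly correlated and associated in
#'     both directions; kitten is moderately correlated with cat and
#'     associated toward it only; mouse is weakly correlated with kitten;
#'     beware is moderately correlated with dog with the association running
#'     beware to dog only (a backward pair when presented dog then beware).
#'     A demonstration vocabulary: the classes are chosen to produce the
#'     canonical orderings (correlation dog-cat > kitten-cat > mouse-kitten;
#'     association forward for kitten, backward for beware), not fitted to
#'     any dataset.}
#'   \item{`neely_3x4`}{Four neighbourhoods of four moderately correlated
#'     concepts (the fourth encoded but unused, keeping the memory count
#'     comparable); every concept of neighbourhood 1 is episodically connected
#'     to every concept of neighbourhood 2 and vice versa (32 links,
#'     salience 0.0336), emulating instructed category-shift expectancies.}
#'   \item{`freq_4x4`}{Four neighbourhoods of four moderately correlated
#'     concepts, no episodic links.}
#'   \item{`mixed_ldt`}{Direct pairs (strongly correlated, forward episodic
#'     link), mediated triples (prime-mediator and mediator-target strongly
#'     correlated, episodic prime-to-mediator link, prime and target
#'     uncorrelated), backward pairs (strongly correlated, episodic link from
#'     target to prime only) and two uncorrelated fillers; 16 patterns total.}
#' }
#'
#' @param name one of `"mixed_vocab"`, `"neely_3x4"`, `"freq_4x4"`,
#'   `"mixed_ldt"`.
#' @param kappa episodic salience for the built-in links.
#' @return a [semantic_structure()].
#' @export
build_named_structure <- function(name = c("mixed_vocab", "neely_3x4",
                                           "freq_4x4", "mixed_ldt"),
                                  kappa = 0.0336) {
  name <- match.arg(name)
  link <- function(source, dest) data.frame(source = source, dest = dest,
                                            kappa = kappa)
  switch(name,
    mixed_vocab = {
      ids <- c("dog", "cat", "kitten", "mouse", "beware",
               paste0("filler", 1:11))
      oc <- data.frame(
        a     = c("dog",    "cat",      "kitten", "dog",
                  "filler1",  "filler2",  "filler4", "filler6"),
        b     = c("cat",    "kitten",   "mouse",  "beware",
                  "filler2",  "filler3",  "filler5", "filler7"),
        class = c("strong", "moderate", "weak",   "moderate",
                  "moderate", "moderate", "weak",    "weak"))
      ep <- rbind(link("dog", "cat"), link("cat", "dog"),
                  link("kitten", "cat"), link("beware", "dog"))
      semantic_structure(ids, oc, ep)
    },
    neely_3x4 = {
      nb <- lapply(1:4, function(i) paste0("nb", i, "_", 1:4))
      ep <- do.call(rbind, c(
        lapply(nb[[1]], function(a) link(a, nb[[2]])),
        lapply(nb[[2]], function(a) link(a, nb[[1]]))))
      neighbourhood_structure(nb, "moderate", ep)
    },
    freq_4x4 = {
      nb <- lapply(1:4, function(i) paste0("nb", i, "_", 1:4))
      neighbourhood_structure(nb, "moderate")
    },
    mixed_ldt = {
      # backward primes get a competing forward associate (b1a/b2a) so that
      # transitions lead away from the backward target at long SOA
      ids <- c("d1p", "d1t", "d2p", "d2t",
               "m1p", "m1m", "m1t", "m2p", "m2m", "m2t",
               "b1p", "b1t", "b1a", "b2p", "b2t", "b2a")
      # d-primes get a competing moderate associate (the a-hubs) so that
      # first transitions only sometimes reach the target, as in normed
      # association strengths well below 1
      oc <- data.frame(
        a = c("d1p", "d2p", "m1p", "m1m", "m2p", "m2m",
              "b1p", "b1p", "b2p", "b2p", "d1p", "d2p"),
        b = c("d1t", "d2t", "m1m", "m1t", "m2m", "m2t",
              "b1t", "b1a", "b2t", "b2a", "b1a", "b2a"),
        class = c(rep("strong", 6), "strong", "moderate",
                  "strong", "moderate", "strong", "strong"))
      # evaluation crossings are verified-unrelated: exactly zero shared
      # units, so related/unrelated contrasts are free of chance-overlap bias
      zero <- data.frame(
        a = c("m1p", "m2p", "d1p", "d2p", "m1p", "m2p",
              "b1p", "b2p", "m1p", "m2p", "m1p", "b1p"),
        b = c("m1t", "m2t", "d2t", "d1t", "d1t", "d2t",
              "b2t", "b1t", "m2t", "m1t", "b2t", "m2t"),
        class = "zero")
      ep <- rbind(link("d1p", "d1t"), link("d2p", "d2t"),
                  link("m1p", "m1m"), link("m2p", "m2m"),
                  link("b1t", "b1p"), link("b2t", "b2p"),
                  link("b1p", "b1a"), link("b2p", "b2a"))
      semantic_structure(ids, rbind(oc, zero), ep)
    })
}

#' Generate the default lexical (word) pattern set
#'
#' Word patterns carry no lexical relations: every pair of words is strictly
#' disjoint, as is the lexical baseline.
#'
#' @param word_ids labels, conventionally one word per concept.
#' @param n_units layer size.
#' @param sparseness word-pattern sparseness.
#' @param seed integer seed.
#' @export
generate_lexical_set <- function(word_ids, n_units = 500, sparseness = 0.04,
                                 seed = 1L) {
  generate_pattern_set(n_units, sparseness,
                       semantic_structure(word_ids), seed = seed,
                       baseline_id = "baseline",
                       unrelated_overlap = "zero")
}
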