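#' Priming effect
#'
#' Difference between unrelated and related reaction times; positive values
#' mean related targets were recognised faster (facilitation of related
#' targets).
#'
#' @param rt_unrelated,rt_related reaction times (ms).
#' @export
priming_effect <- function(rt_unrelated, rt_related) {
  stopifnot(is.finite(rt_unrelated), is.finite(rt_related))
  rt_unrelated - rt_related
}

#' Facilitation / inhibition relative to neutral
#'
#' `rt_neutral - rt_condition`: positive values indicate facilitation,
#' negative values inhibition, relative to neutral-prime trials.
#'
#' @param rt_condition,rt_neutral reaction times (ms).
#' @export
facilitation_inhibition <- function(rt_condition, rt_neutral) {
  stopifnot(is.finite(rt_condition), is.finite(rt_neutral))
  rt_neutral - rt_condition
}

#' Summarise per-trial records into condition cells
#'
#' Aggregates reaction times per condition label (and SOA), excluding
#' timeouts, and reports the centre, the standard error (n - 1 denominator)
#' and the counts. Simulated summaries default to means over seeded trials;
#' a median mode mirrors the per-subject-median convention of the human
#' analyses.
#'
#' @param records data frame with at least `condition`, `soa`, `rt`,
#'   `timeout` columns ([run_experiment()] records qualify).
#' @param aggregate `"mean"` or `"median"`.
#' @return data frame with one row per (condition, soa) cell: `rt`, `sem`,
#'   `n`, `n_timeout`; all-timeout cells are kept but flagged with `NA` rt.
#' @export
summarize_experiment <- function(records, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("condition", "soa", "rt", "timeout") %in% names(records)))
  cells <- unique(records[, c("condition", "soa")])
  cells <- cells[order(cells$condition, cells$soa), , drop = FALSE]
  agg <- if (aggregate == "mean") mean else median
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$condition == cells$condition[i] &
      records$soa == cells$soa[i]
    ok <- sel & !records$timeout
    rts <- records$rt[ok]
    data.frame(condition = cells$condition[i], soa = cells$soa[i],
               rt = if (length(rts) > 0) agg(rts) else NA_real_,
               sem = if (length(rts) > 1) sd(rts) / sqrt(length(rts)) else NA_real_,
               n = sum(ok), n_timeout = sum(sel & records$timeout))
  }))
  rownames(out) <- NULL
  out
}

#' Priming summary: effects against unrelated and neutral baselines
#'
#' Computes, for each SOA, the priming effect (unrelated minus related) and,
#' when a neutral cell exists, the facilitation and inhibition components
#' around it. By construction the priming effect decomposes as
#' facilitation(related) - facilitation(unrelated).
#'
#' @param summary a [summarize_experiment()] result with condition labels
#'   `related`, `unrelated` and optionally `neutral`.
#' @return data frame per SOA with `priming`, `priming_sem`, `facilitation`
#'   (related vs neutral) and `inhibition` (unrelated vs neutral, negative =
#'   slowing).
#' @export
priming_summary <- function(summary) {
  soas <- sort(unique(summary$soa))
  cell <- function(cond, soa) {
    r <- summary[summary$condition == cond & summary$soa == soa, ]
    if (nrow(r) == 0) r <- data.frame(rt = NA_real_, sem = NA_real_)
    r
  }
  do.call(rbind, lapply(soas, function(s) {
    rel <- cell("related", s); unr <- cell("unrelated", s)
    neu <- cell("neutral", s)
    data.frame(
      soa = s,
      priming = unr$rt - rel$rt,
      priming_sem = sqrt(sum(c(rel$sem, unr$sem)^2, na.rm = TRUE)),
      facilitation = neu$rt - rel$rt,
      inhibition = neu$rt - unr$rt)
  }))
}

# Embedded human reaction-time reference tables (mean RTs across subjects,
# ms). Experiment 1: lexical decision, 3 SOAs x direct/mediated/backward x
# expectancy induced/not induced. Experiment 2: masked primes, brief SOAs.
human_rt_cells <- function(table) {
  if (table == "table1") {
    g <- expand.grid(
      primetype = c("related", "unrelated"),
      expectancy = c("induced", "not_induced"),
      relation = c("direct", "mediated", "backward"),
      soa = c(250, 550, 1000), stringsAsFactors = FALSE)
    g <- g[, c("relation", "expectancy", "soa", "primetype")]
    # column order: related, unrelated within induced then not_induced,
    # relations direct, mediated, backward, blocks by SOA
    g$rt <- c(489, 565, 548, 582,  531, 560, 568, 565,  537, 594, 544, 583,
              518, 564, 507, 524,  551, 563, 525, 523,  569, 607, 517, 550,
              467, 555, 533, 564,  519, 539, 564, 560,  542, 552, 560, 560)
    g
  } else {
    g <- expand.grid(
      primetype = c("related", "unrelated"),
      relation = c("direct", "mediated", "backward"),
      soa = c(50, 150), stringsAsFactors = FALSE)
    g <- data.frame(relation = g$relation, expectancy = "n/a",
                    soa = g$soa, primetype = g$primetype)
    g$rt <- c(550, 582,  560, 559,  574, 590,
              533, 575,  537, 555,  561, 588)
    g
  }
}

human_rt_priming <- function(table) {
  if (table == "table1") {
    d <- expand.grid(
      expectancy = c("induced", "not_induced"),
      relation = c("direct", "mediated", "backward"),
      soa = c(250, 550, 1000), stringsAsFactors = FALSE)
    d <- d[, c("relation", "expectancy", "soa")]
    d$priming <- c(76, 34,  29, -3,  57, 39,
                   46, 17,  12, -2,  38, 33,
                   88, 31,  20, -4,  10, 0)
    d
  } else {
    d <- expand.grid(
      relation = c("direct", "mediated", "backward"),
      soa = c(50, 150), stringsAsFactors = FALSE)
    d <- data.frame(relation = d$relation, expectancy = "n/a", soa = d$soa)
    d$priming <- c(32, -1, 16,  42, 18, 27)
    d
  }
}

#' Embedded human reaction-time tables
#'
#' Mean reaction times across subjects (ms) from the two reference lexical
#' decision experiments: `"table1"` (SOA 250/550/1000 ms, expectancy induced
#' vs not induced, direct/mediated/backward relatedness) and `"table2"`
#' (masked primes, SOA 50/150 ms). The printed priming rows are attached as
#' `attr(, "priming")` for cross-checks; `priming_effect()` over the cells
#' reproduces them exactly.
#'
#' @param table `"table1"` or `"table2"`.
#' @return data frame with columns `relation`, `expectancy`, `soa`,
#'   `primetype`, `rt`.
#' @export
load_human_fixture <- function(table = c("table1", "table2")) {
  table <- match.arg(table)
  cells <- human_rt_cells(table)
  stopifnot(all(cells$rt > 0))
  attr(cells, "priming") <- human_rt_priming(table)
  cells
}

#' Priming effects computed from a human fixture
#'
#' @param cells a [load_human_fixture()] result.
#' @return data frame per (relation, expectancy, soa) with the computed
#'   `priming` (unrelated minus related).
#' @export
fixture_priming_effects <- function(cells) {
  keys <- unique(cells[, c("relation", "expectancy", "soa")])
  keys$priming <- vapply(seq_len(nrow(keys)), function(i) {
    sel <- cells$relation == keys$relation[i] &
      cells$expectancy == keys$expectancy[i] & cells$soa == keys$soa[i]
    priming_effect(cells$rt[sel & cells$primetype == "unrelated"],
                   cells$rt[sel & cells$primetype == "related"])
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}
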