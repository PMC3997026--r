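test_that("generated patterns have exact sparseness and designated overlaps", {
  struct <- build_named_structure("mixed_vocab")
  for (mode in c("chance", "zero")) {
    ps <- generate_pattern_set(500, 0.06, struct, seed = 3,
                               unrelated_overlap = mode)
    expect_true(all(lengths(ps$units) == 30))
    expect_true(all(unlist(ps$units) >= 1 & unlist(ps$units) <= 500))
    # designated pairs: exact counts from the class fractions
    oc <- struct$overlap_class
    want <- c(strong = 3L, moderate = 2L, weak = 1L)
    for (i in seq_len(nrow(oc))) {
      expect_identical(overlap_count(oc$a[i], oc$b[i], set = ps),
                       unname(want[oc$class[i]]),
                       label = paste(oc$a[i], oc$b[i]))
    }
  }
})

test_that("zero mode makes all undesignated pairs and the baseline disjoint", {
  struct <- semantic_structure(paste0("w", 1:10))
  ps <- generate_pattern_set(500, 0.04, struct, seed = 5,
                             unrelated_overlap = "zero")
  ids <- names(ps$units)
  for (i in seq_along(ids)[-1])
    for (j in seq_len(i - 1))
      expect_identical(overlap_count(ids[i], ids[j], set = ps), 0L)
})

test_that("chance mode caps undesignated overlaps and keeps chance-level reuse", {
  struct <- build_named_structure("freq_4x4")
  ps <- generate_pattern_set(500, 0.06, struct, seed = 9)
  ids <- names(ps$units)
  oc <- struct$overlap_class
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  designated <- key(oc$a, oc$b)
  ovs <- utils::combn(ids, 2, function(pr) {
    o <- overlap_count(pr[1], pr[2], set = ps)
    if (key(pr[1], pr[2])[1] %in% designated) NA_integer_ else o
  })
  expect_true(all(ovs[!is.na(ovs)] <= 2))
  expect_gt(mean(ovs[!is.na(ovs)]), 0.5)  # genuinely chance-level, not disjoint
})

test_that("pattern generation is deterministic in the seed", {
  struct <- build_named_structure("mixed_ldt")
  a <- generate_pattern_set(500, 0.06, struct, seed = 7)
  b <- generate_pattern_set(500, 0.06, struct, seed = 7)
  c <- generate_pattern_set(500, 0.06, struct, seed = 8)
  expect_identical(a$units, b$units)
  expect_false(identical(a$units, c$units))
})

test_that("infeasible overlap demands raise constraint errors", {
  # per-pattern demand exceeding the pattern size
  frac <- c(strong = 0.9, moderate = 0.5, weak = 0.033, none = 0)
  oc <- data.frame(a = c("a", "a"), b = c("b", "c"),
                   class = c("strong", "moderate"))
  st <- semantic_structure(c("a", "b", "c"), oc, fractions = frac)
  expect_error(generate_pattern_set(20, 0.5, st, seed = 1), "infeasible|shared")
  # total distinct units exceeding the layer (zero mode)
  st2 <- semantic_structure(paste0("w", 1:30))
  expect_error(generate_pattern_set(100, 0.2, st2, seed = 1,
                                    unrelated_overlap = "zero"),
               "infeasible")
})

test_that("make_baseline_pattern yields zero overlap or a counting error", {
  ps <- generate_pattern_set(200, 0.1, semantic_structure(paste0("w", 1:8)),
                             seed = 2, baseline_id = NULL,
                             unrelated_overlap = "zero")
  ps2 <- make_baseline_pattern(ps, seed = 4, id = "base")
  for (id in setdiff(names(ps2$units), "base"))
    expect_identical(overlap_count("base", id, set = ps2), 0L)
  # 9 patterns x 20 units = 180 of 200 used; a tenth fits, an eleventh cannot
  ps3 <- make_baseline_pattern(ps2, seed = 4, id = "base2")
  expect_error(make_baseline_pattern(ps3, seed = 4, id = "base3"),
               "unused units")
})

test_that("self- and mismatched-overlap behave as documented", {
  ps <- generate_pattern_set(500, 0.06, build_named_structure("mixed_vocab"),
                             seed = 42)
  u <- pattern_units(ps, "dog")
  expect_identical(overlap_count(u, u), length(u))
  expect_error(pattern_units(ps, "no_such_pattern"), "unknown")
})

test_that("named structures have the documented shapes", {
  ne <- build_named_structure("neely_3x4")
  expect_length(ne$pattern_ids, 16)
  expect_identical(nrow(ne$episodic_links), 32L)
  expect_true(all(ne$episodic_links$kappa == 0.0336))
  # links connect neighbourhoods 1 and 2 in both directions
  expect_true(all(grepl("^nb[12]_", ne$episodic_links$source)))
  expect_true(all(substr(ne$episodic_links$source, 3, 3) !=
                  substr(ne$episodic_links$dest, 3, 3)))

  fr <- build_named_structure("freq_4x4")
  expect_length(fr$pattern_ids, 16)
  expect_identical(nrow(fr$episodic_links), 0L)
  expect_identical(nrow(fr$overlap_class), 24L)  # 4 neighbourhoods x C(4,2)

  f1 <- build_named_structure("mixed_vocab")
  expect_length(f1$pattern_ids, 16)
  expect_identical(semlatch:::overlap_class_of(f1, "dog", "cat"), "strong")

  expect_error(build_named_structure("nope"))
})

test_that("structures and pattern sets serialise and round-trip", {
  st <- build_named_structure("mixed_ldt")
  st2 <- read_structure(write_structure(st))
  expect_identical(st2$pattern_ids, st$pattern_ids)
  expect_identical(st2$overlap_class$class, st$overlap_class$class)
  expect_equal(st2$episodic_links$kappa, st$episodic_links$kappa)

  ps <- generate_pattern_set(500, 0.06, st, seed = 11)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_pattern_set(ps, path)
  ps2 <- read_pattern_set(path)
  expect_identical(ps2$units, ps$units)
  expect_identical(ps2$baseline_id, ps$baseline_id)
  expect_equal(ps2$n_units, ps$n_units)
})
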