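sized_records <- function(...) {
  rec <- rbind(...)
  rec$specimen_id <- sprintf("C%03d", seq_len(nrow(rec)))
  impute_sizes(as_specimens(rec), quiet = TRUE)
}

test_that("sample mean size reports mean, type-7 quartiles and count per level", {
  rec <- sized_records(specimens_from_sizes("A sp.", "S1", 1, 3.0),
                       specimens_from_sizes("B sp.", "S2", 2, c(1, 2, 3, 4)))
  s <- sample_mean_size(rec, "all")
  expect_s3_class(s, "sample_series")
  expect_equal(s$value, c(3.0, 2.5))
  expect_equal(s$q1[1], 3.0)
  expect_equal(s$q3[1], 3.0)
  expect_equal(s$n, c(1, 4))
  expect_equal(s$q1[2], unname(quantile(1:4, 0.25, type = 7)))
  expect_equal(s$q3[2], unname(quantile(1:4, 0.75, type = 7)))
  expect_true(all(diff(s$strat_height) > 0))
})

test_that("group filters restrict to the clade tally and empty groups error", {
  rec <- sized_records(
    specimens_from_sizes("Biv sp.", "S1", 1, c(3, 3.5), clade = "bivalve"),
    specimens_from_sizes("Brach sp.", "S1", 1, 4.2, clade = "brachiopod"))
  expect_equal(sum(sample_mean_size(rec, "bivalves")$n), 2)
  expect_equal(sum(sample_mean_size(rec, "brachiopods")$n), 1)
  biv_only <- rec[rec$clade == "bivalve", ]
  expect_error(sample_mean_size(biv_only, "brachiopods"), "no retained records")
})

test_that("community mean lies between subgroup means where both are present", {
  ds <- simulate_dataset(simulation_config(seed = 77L))
  sp <- suppressMessages(impute_sizes(ds$specimens, quiet = TRUE))
  all_s <- sample_mean_size(sp, "all")
  biv <- sample_mean_size(sp, "bivalves")
  bra <- sample_mean_size(sp, "brachiopods")
  shared <- Reduce(intersect, list(all_s$sample_id, biv$sample_id, bra$sample_id))
  for (id in shared) {
    v <- all_s$value[all_s$sample_id == id]
    lo <- min(biv$value[biv$sample_id == id], bra$value[bra$sample_id == id])
    hi <- max(biv$value[biv$sample_id == id], bra$value[bra$sample_id == id])
    expect_true(v >= lo - 1e-12 && v <= hi + 1e-12)
  }
})

test_that("three-point moving average shrinks its window at the endpoints", {
  s <- data.frame(value = c(1, 2, 3, 4))
  expect_equal(moving_average_3(s)$value, c(1.5, 2, 3, 3.5))
  const <- data.frame(value = rep(2.2, 7))
  expect_equal(moving_average_3(const)$value, rep(2.2, 7))
  single <- data.frame(value = 5)
  expect_equal(moving_average_3(single)$value, 5)
})

test_that("common-species filter matches brute-force enumeration and its boundary", {
  ## five constructed species with varying per-level counts
  counts <- list(
    alpha = c(S1 = 3, S2 = 3, S3 = 3),        # boundary: exactly 3x3 -> in
    beta  = c(S1 = 3, S2 = 3),                # only 2 qualifying levels -> out
    gamma = c(S1 = 5, S2 = 1, S3 = 4, S4 = 6),# 3 qualifying levels -> in
    delta = c(S1 = 2, S2 = 2, S3 = 2, S4 = 2),# never >= 3 per level -> out
    eps   = c(S1 = 9),                         # 1 level -> out
    zeta  = c(S1 = 3, S2 = 1, S3 = 1)          # sparse levels: reading-dependent
  )
  heights <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4)
  rec <- do.call(rbind, lapply(names(counts), function(sp) {
    do.call(rbind, lapply(names(counts[[sp]]), function(s) {
      specimens_from_sizes(sp, s, heights[[s]], rep(3, counts[[sp]][[s]]))
    }))
  }))
  rec$specimen_id <- sprintf("N%03d", seq_len(nrow(rec)))
  rec <- impute_sizes(as_specimens(rec), quiet = TRUE)

  ## brute-force oracle straight from the definition
  oracle <- names(counts)[vapply(counts, function(ct)
    sum(ct >= 3) >= 3, logical(1))]
  expect_setequal(common_species(rec), oracle)
  expect_true("alpha" %in% common_species(rec))
  expect_false("beta" %in% common_species(rec))

  ## lenient reading counts sparse occupied levels towards min_levels
  lenient <- common_species(rec, rule = "lenient")
  expect_true("zeta" %in% lenient)       # 3 occupied levels, one with >= 3
  expect_false("zeta" %in% common_species(rec))
  expect_false("delta" %in% lenient)     # no level ever reaches 3 specimens
})

test_that("relaxing the filter thresholds never removes a species", {
  ds <- simulate_dataset(simulation_config(seed = 99L))
  rec <- suppressMessages(impute_sizes(ds$specimens, quiet = TRUE))
  base <- common_species(rec, 3, 3)
  expect_true(all(base %in% common_species(rec, 2, 3)))
  expect_true(all(base %in% common_species(rec, 3, 2)))
  expect_true(all(base %in% common_species(rec, 1, 1)))
})

test_that("size classification splits species around the mean of species means", {
  rec <- sized_records(
    specimens_from_sizes("small1", "S1", 1, rep(2, 3)),
    specimens_from_sizes("small2", "S1", 1, rep(3, 3)),
    specimens_from_sizes("big", "S1", 1, rep(7, 3)))
  cls <- classify_species_size(rec, c("small1", "small2", "big"))
  expect_equal(attr(cls, "cutoff"), 4)
  expect_equal(cls$class[cls$taxon == "big"], "larger")
  expect_equal(sum(cls$class == "smaller"), 2)

  ## degenerate tie: identical means -> all "smaller" under the strict rule
  tie <- sized_records(specimens_from_sizes("t1", "S1", 1, rep(3, 2)),
                       specimens_from_sizes("t2", "S1", 1, rep(3, 2)))
  cls2 <- classify_species_size(tie, c("t1", "t2"))
  expect_true(all(cls2$class == "smaller"))

  expect_error(classify_species_size(rec, "big"), "at least 2")
})

test_that("percent larger-sized matches hand enumeration and stays in [0, 100]", {
  rec <- sized_records(
    specimens_from_sizes("big", "S1", 1, rep(7, 3)),      # 3 larger in S1
    specimens_from_sizes("small1", "S1", 1, 2),           # 1 smaller in S1
    specimens_from_sizes("small1", "S2", 2, rep(2, 5)),   # 5 smaller in S2
    specimens_from_sizes("small2", "S2", 2, rep(3, 2)))
  cls <- classify_species_size(rec, c("big", "small1", "small2"))
  pct <- percent_larger(rec, cls, "all")
  expect_equal(pct$value, c(75, 0))
  expect_equal(pct$n, c(4, 7))
  expect_true(all(pct$value >= 0 & pct$value <= 100))

  ds <- simulate_dataset(simulation_config(seed = 17L))
  sp <- suppressMessages(impute_sizes(ds$specimens, quiet = TRUE))
  cs <- common_species(sp)
  cls2 <- classify_species_size(sp, cs)
  p2 <- percent_larger(sp, cls2, "all")
  expect_true(all(p2$value >= 0 & p2$value <= 100))
})
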