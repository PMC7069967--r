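test_that("configuration validation rejects impossible settings", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_levels = 3))
  expect_error(simulation_config(missing_fraction = 1))
  expect_error(simulation_config(excursion = c(5, 40)))
})

test_that("isotope simulation honours amplitude, noise and determinism", {
  quiet_cfg <- simulation_config(excursion_amplitude = 0, d18O_process_sd = 0,
                                 d18O_noise_sd = 0, seed = 1L)
  iso <- simulate_isotopes(quiet_cfg)
  expect_equal(iso$truth$d18O_true, rep(quiet_cfg$d18O_baseline, 30))
  expect_equal(unique(iso$measurements$d18O), quiet_cfg$d18O_baseline)

  cfg <- simulation_config(seed = 2L)
  iso2 <- simulate_isotopes(cfg)
  in_ev <- iso2$levels$in_event
  m <- iso2$measurements
  lvl_mean <- tapply(m$d18O, m$sample_id, mean)[iso2$levels$sample_id]
  shift <- mean(lvl_mean[in_ev]) - mean(lvl_mean[!in_ev])
  se <- sqrt(var(lvl_mean[in_ev]) / sum(in_ev) +
             var(lvl_mean[!in_ev]) / sum(!in_ev))
  expect_lt(abs(shift - cfg$excursion_amplitude), 2 * se + 0.05)

  expect_identical(simulate_isotopes(cfg), iso2)
  ## true temperatures follow the thermometer applied to true d18O
  expect_equal(iso2$truth$temperature, calcite_temperature(iso2$truth$d18O_true))
})

test_that("community simulation draws the configured count and responds to beta_abund", {
  cfg0 <- simulation_config(seed = 3L, beta_abund = 0, beta_size = 0)
  iso <- simulate_isotopes(cfg0)
  com <- simulate_community(cfg0, iso$truth$temperature, iso$levels)
  tab <- table(com$records$sample_id)
  expect_true(all(tab == cfg0$individuals_per_level))
  expect_error(simulate_community(cfg0, iso$truth$temperature, iso$levels,
                                  pool = data.frame()), "empty species pool")
})

test_that("a null community shows no systematic event-interval size change", {
  flat <- vapply(1:100, function(i) {
    cfg <- simulation_config(seed = 500L + i, beta_abund = 0, beta_size = 0,
                             missing_fraction = 0)
    iso <- simulate_isotopes(cfg)
    com <- simulate_community(cfg, iso$truth$temperature, iso$levels)
    size <- log2(sqrt(com$records$dim_a * com$records$dim_b))
    lvl <- tapply(size, com$records$sample_id, mean)[iso$levels$sample_id]
    t.test(lvl[iso$levels$in_event], lvl[!iso$levels$in_event])$p.value
  }, numeric(1))
  expect_gte(mean(flat > 0.05), 0.90)
})

test_that("a negative abundance effect depresses in-event community size", {
  smaller <- vapply(1:25, function(i) {
    cfg <- simulation_config(seed = 600L + i, missing_fraction = 0)
    iso <- simulate_isotopes(cfg)
    com <- simulate_community(cfg, iso$truth$temperature, iso$levels)
    size <- log2(sqrt(com$records$dim_a * com$records$dim_b))
    lvl <- tapply(size, com$records$sample_id, mean)[iso$levels$sample_id]
    mean(lvl[iso$levels$in_event]) < mean(lvl[!iso$levels$in_event])
  }, logical(1))
  expect_gte(mean(smaller), 0.95)
})

test_that("the two size-change mechanisms are separable in the generator", {
  gen <- function(ba, bs) {
    cfg <- simulation_config(seed = 44L, beta_abund = ba, beta_size = bs,
                             missing_fraction = 0)
    ds <- simulate_dataset(cfg)
    sp <- suppressMessages(impute_sizes(ds$specimens, quiet = TRUE))
    cls <- classify_species_size(sp, common_species(sp))
    pct <- percent_larger(sp, cls, "all")
    ev <- ds$levels$sample_id[ds$levels$in_event]
    d_pct <- mean(pct$value[pct$sample_id %in% ev]) -
      mean(pct$value[!(pct$sample_id %in% ev)])
    ## within-species deviation from the species generating mean
    dev <- sp$size_log2 - ds$truth$pool$mean_log2[match(sp$taxon,
                                                        ds$truth$pool$taxon)]
    d_within <- mean(dev[sp$sample_id %in% ev]) - mean(dev[!(sp$sample_id %in% ev)])
    c(d_pct = d_pct, d_within = d_within)
  }
  size_only <- gen(0, -0.1)
  expect_lt(size_only[["d_within"]], -0.15)   # plastic shrinkage expressed
  expect_lt(abs(size_only[["d_pct"]]), 10)    # composition nearly unchanged
  abund_only <- gen(-0.3, 0)
  expect_lt(abund_only[["d_pct"]], -15)       # composition shifts strongly
  expect_lt(abs(abund_only[["d_within"]]), 0.08)
})

test_that("missingness masks the requested fraction and is reproducible", {
  cfg <- simulation_config(seed = 5L, missing_fraction = 0)
  iso <- simulate_isotopes(cfg)
  com <- simulate_community(cfg, iso$truth$temperature, iso$levels)
  rec <- com$records
  expect_identical(apply_missingness(rec, 0), rec)
  m1 <- apply_missingness(rec, 0.3, seed = 10L)
  expect_equal(sum(!m1$measured), round(0.3 * nrow(rec)))
  expect_true(all(is.na(m1$dim_a[!m1$measured])))
  expect_identical(apply_missingness(rec, 0.3, seed = 10L), m1)
  ## every species keeps at least one measured specimen when possible
  kept <- tapply(m1$measured, m1$taxon, any)
  expect_true(all(kept))
  ## binomial mode is close to the nominal fraction
  m2 <- apply_missingness(rec, 0.3, seed = 11L, mode = "binomial")
  expect_lt(abs(mean(!m2$measured) - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(rec)))
})

test_that("a full dataset regenerates bit-identically from the same config", {
  cfg <- simulation_config(seed = 123L)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})
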