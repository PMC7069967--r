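## In-code fixtures shared across test files.

toy_specimens <- function() {
  data.frame(
    specimen_id = sprintf("S%02d", 1:6),
    sample_id = c("A", "A", "A", "B", "B", "C"),
    strat_height = c(1, 1, 1, 2.5, 2.5, 4),
    taxon = c("Plagiostoma giganteum", "Plagiostoma giganteum",
              "Soaresirhynchia bouchardi", "Plagiostoma giganteum",
              "Soaresirhynchia bouchardi", "Soaresirhynchia bouchardi"),
    clade = c("bivalve", "bivalve", "brachiopod", "bivalve", "brachiopod",
              "brachiopod"),
    valve = c("left", "right", "ventral", "articulated", "dorsal", "ventral"),
    dim_a = c(16, 8, 9, 12, 10, 11),
    dim_b = c(9, 2, 4, 3, 10, 11),
    measured = TRUE,
    stringsAsFactors = FALSE
  )
}

## Specimen rows built from explicit log2 sizes (dim_a = dim_b = 2^size so
## the geometric mean is exactly 2^size).
specimens_from_sizes <- function(taxon, sample_id, strat_height, size_log2,
                                 clade = "bivalve", measured = TRUE) {
  n <- length(size_log2)
  meas <- rep_len(measured, n)
  dims <- 2^size_log2
  dims[!meas] <- NA_real_
  data.frame(
    specimen_id = sprintf("X%03d", seq_len(n)),
    sample_id = sample_id,
    strat_height = strat_height,
    taxon = taxon,
    clade = clade,
    valve = "unknown",
    dim_a = dims,
    dim_b = dims,
    measured = meas,
    stringsAsFactors = FALSE
  )
}

## Mean size series and d18O series for one simulated dataset, on the level
## grid, ready for the correlation pipeline.
pipeline_inputs <- function(seed, beta_abund = -0.3, beta_size = -0.03, ...) {
  cfg <- simulation_config(seed = seed, beta_abund = beta_abund,
                           beta_size = beta_size, ...)
  ds <- simulate_dataset(cfg)
  sp <- suppressMessages(impute_sizes(drop_rare_groups(ds$specimens,
                                                       quiet = TRUE),
                                      quiet = TRUE))
  ss <- sample_mean_size(sp, "all")
  iso <- aggregate_isotopes(screen_measurements(ds$isotopes), ds$levels)
  y <- rep(NA_real_, nrow(ds$levels))
  y[match(ss$sample_id, ds$levels$sample_id)] <- ss$value
  x <- rep(NA_real_, nrow(ds$levels))
  x[match(iso$sample_id, ds$levels$sample_id)] <- iso$d18O_mean
  list(size = y, d18O = x, dataset = ds, specimens = sp)
}
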