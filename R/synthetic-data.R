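#' Simulation configuration
#'
#' Parameters of the synthetic fossil-community and isotope generator. The
#' defaults emulate the statistical structure of a ~28 m epicontinental
#' section sampled at ~30 levels across a negative oxygen-isotope excursion:
#' a two-clade species pool with lognormal within-species size variation,
#' per-level multinomial abundances whose weights for larger species decline
#' as temperature rises, a modest within-species plastic size response, and
#' ~30% of specimens left unmeasured.
#'
#' Key effect sizes (chosen to mirror the magnitudes the analysis is designed
#' to detect): the excursion shifts d18O by `excursion_amplitude` permil
#' (default -1, i.e. ~+3.5 degC of warming); `beta_abund` (default -0.3 per
#' degC per log2-unit of size deviation) tilts community composition so that
#' a 3.5 degC warming moves the community mean size down by roughly
#' `|beta_abund| * dT * var(species means)` = 0.67 log2 units, matching a
#' visible community-scale size drop; `beta_size` (default -0.03 log2/degC)
#' keeps within-species change minor (~0.1 log2 over the excursion), the
#' subordinate mechanism.
#'
#' @param n_levels Number of ordered sample levels (default 30).
#' @param level_spacing Stratigraphic spacing between levels, m (default 1).
#' @param excursion Integer `c(start, end)` level indices of the excursion
#'   interval (default `c(11, 20)`).
#' @param d18O_baseline Pre-excursion calcite d18O, permil V-PDB (default -1).
#' @param excursion_amplitude Excursion shift in d18O, permil; negative for
#'   warming (default -1).
#' @param d18O_process_sd Level-to-level (smoothed) geological noise sd,
#'   permil (default 0.1).
#' @param d18O_noise_sd Per-specimen analytical + intrashell noise sd,
#'   permil (default 0.15).
#' @param iso_per_level Isotope specimens measured per level (default 4).
#' @param n_bivalve_species,n_brachiopod_species Species-pool sizes
#'   (defaults 12 and 6).
#' @param species_mean_log2,species_sd_log2 Normal distribution of species
#'   mean log2 sizes (defaults 3.5 and 0.8 log2 mm, i.e. geometric means
#'   ~4-30 mm).
#' @param within_sd_log2 Within-species size sd on the log2 scale
#'   (default 0.5), making sizes lognormal in mm.
#' @param base_weight_sd Lognormal sd of species base abundances
#'   (default 0.5).
#' @param individuals_per_level Individuals collected per level (default 100,
#'   emulating standardised bulk sampling).
#' @param beta_abund Abundance effect: change in a species' log weight per
#'   degC of warming per log2-unit that the species mean exceeds the pool
#'   mean (default -0.3).
#' @param beta_size Within-species plastic response, log2 size per degC
#'   (default -0.03).
#' @param missing_fraction Fraction of specimens left unmeasured
#'   (default 0.3).
#' @param missing_mode `"exact"` (default; exactly `round(fraction * n)`
#'   hidden) or `"binomial"`.
#' @param missing_size_bias Log-odds change of being hidden per log2-unit of
#'   size (default 0 = completely at random).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_levels = 30, level_spacing = 1,
                              excursion = c(11, 20),
                              d18O_baseline = -1.0, excursion_amplitude = -1.0,
                              d18O_process_sd = 0.1, d18O_noise_sd = 0.15,
                              iso_per_level = 4,
                              n_bivalve_species = 12, n_brachiopod_species = 6,
                              species_mean_log2 = 3.5, species_sd_log2 = 0.8,
                              within_sd_log2 = 0.5, base_weight_sd = 0.5,
                              individuals_per_level = 100,
                              beta_abund = -0.3, beta_size = -0.03,
                              missing_fraction = 0.3,
                              missing_mode = c("exact", "binomial"),
                              missing_size_bias = 0,
                              seed = NULL) {
  cfg <- list(n_levels = n_levels, level_spacing = level_spacing,
              excursion = excursion, d18O_baseline = d18O_baseline,
              excursion_amplitude = excursion_amplitude,
              d18O_process_sd = d18O_process_sd, d18O_noise_sd = d18O_noise_sd,
              iso_per_level = iso_per_level,
              n_bivalve_species = n_bivalve_species,
              n_brachiopod_species = n_brachiopod_species,
              species_mean_log2 = species_mean_log2,
              species_sd_log2 = species_sd_log2,
              within_sd_log2 = within_sd_log2, base_weight_sd = base_weight_sd,
              individuals_per_level = individuals_per_level,
              beta_abund = beta_abund, beta_size = beta_size,
              missing_fraction = missing_fraction,
              missing_mode = match.arg(missing_mode),
              missing_size_bias = missing_size_bias,
              seed = seed)
  with(cfg, {
    stopifnot(n_levels >= 4, level_spacing > 0,
              length(excursion) == 2, excursion[1] >= 1,
              excursion[2] <= n_levels, excursion[1] <= excursion[2],
              d18O_process_sd >= 0, d18O_noise_sd >= 0, iso_per_level >= 1,
              n_bivalve_species + n_brachiopod_species >= 1,
              species_sd_log2 >= 0, within_sd_log2 >= 0, base_weight_sd >= 0,
              individuals_per_level >= 1,
              missing_fraction >= 0, missing_fraction < 1)
  })
  structure(cfg, class = "simulation_config")
}

level_ids <- function(n) sprintf("L%02d", seq_len(n))

#' Simulate the isotope record
#'
#' Per level, the true calcite d18O is the baseline plus the excursion
#' amplitude inside the excursion window, plus smooth geological noise
#' (white noise passed through a centred three-point mean). Each of
#' `iso_per_level` specimen measurements adds independent observation noise.
#' True temperatures follow from the thermometer equation.
#'
#' @param config A [simulation_config()].
#' @param params Thermometer parameters.
#' @return List with `measurements` (isotope data frame), `levels`
#'   (`sample_id,strat_height,in_event`) and `truth`
#'   (`sample_id,d18O_true,temperature`).
#' @export
simulate_isotopes <- function(config, params = thermometer_params()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_levels
  ids <- level_ids(n)
  in_ev <- seq_len(n) >= config$excursion[1] & seq_len(n) <= config$excursion[2]
  noise <- stats::rnorm(n, 0, config$d18O_process_sd)
  smooth <- vapply(seq_len(n), function(i)
    mean(noise[max(1, i - 1):min(n, i + 1)]), numeric(1))
  d18O_true <- config$d18O_baseline + config$excursion_amplitude * in_ev + smooth
  temp <- calcite_temperature(d18O_true, params)
  d13C_true <- 1.5 - 3.0 * in_ev  # negative carbon excursion delimits the event
  meas <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- config$iso_per_level
    data.frame(
      sample_id = ids[i],
      substrate = rep_len(c("rhynchonellid", "oyster"), k),
      d18O = d18O_true[i] + stats::rnorm(k, 0, config$d18O_noise_sd),
      d13C = d13C_true[i] + stats::rnorm(k, 0, config$d18O_noise_sd),
      mn_ca = stats::runif(k, 0, 0.08),
      fe_ca = stats::runif(k, 0, 0.8),
      stringsAsFactors = FALSE)
  }))
  meas$accepted <- TRUE
  levels <- data.frame(sample_id = ids,
                       strat_height = (seq_len(n) - 1) * config$level_spacing,
                       in_event = in_ev, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, d18O_true = d18O_true,
                      temperature = temp, stringsAsFactors = FALSE)
  list(measurements = meas, levels = levels, truth = truth)
}

make_species_pool <- function(config) {
  nb <- config$n_bivalve_species; nr <- config$n_brachiopod_species
  k <- nb + nr
  data.frame(
    taxon = c(sprintf("Bivalvia sp. %02d", seq_len(nb)),
              sprintf("Brachiopoda sp. %02d", seq_len(nr))),
    clade = c(rep("bivalve", nb), rep("brachiopod", nr)),
    mean_log2 = stats::rnorm(k, config$species_mean_log2, config$species_sd_log2),
    base_logw = stats::rnorm(k, 0, config$base_weight_sd),
    stringsAsFactors = FALSE)
}

#' Simulate specimen records of a community time series
#'
#' Per level, species abundances are multinomial with log-weights
#' `base + beta_abund * (T - T_ref) * (species mean - pool mean)`: warming
#' depresses the weights of larger-than-average species, the
#' composition-change mechanism, while per-level totals stay fixed. Each
#' individual's log2 geometric-mean size is normal with mean
#' `species mean + beta_size * (T - T_ref)` (within-species plasticity) and
#' sd `within_sd_log2`; its two dimensions are recovered from the size and a
#' lognormal aspect ratio. `T_ref` is the temperature implied by the
#' baseline d18O.
#'
#' @param config A [simulation_config()].
#' @param temperatures Numeric vector of true temperatures per level.
#' @param levels Level table as produced by [simulate_isotopes()].
#' @param pool Optional pre-drawn species pool (for reuse across replicates).
#' @return List `records` (specimen data frame, all measured) and `pool`
#'   (species table with the generating truth).
#' @export
simulate_community <- function(config, temperatures, levels, pool = NULL) {
  if (is.null(pool)) pool <- make_species_pool(config)
  if (!nrow(pool)) stop("empty species pool", call. = FALSE)
  t_ref <- calcite_temperature(config$d18O_baseline)
  pool_mean <- mean(pool$mean_log2)
  n <- config$n_levels
  out <- vector("list", n)
  for (i in seq_len(n)) {
    dT <- temperatures[i] - t_ref
    logw <- pool$base_logw + config$beta_abund * dT * (pool$mean_log2 - pool_mean)
    w <- exp(logw - max(logw))
    counts <- as.integer(stats::rmultinom(1, config$individuals_per_level,
                                          w / sum(w)))
    sp_idx <- rep(seq_len(nrow(pool)), counts)
    m <- length(sp_idx)
    size <- stats::rnorm(m, pool$mean_log2[sp_idx] + config$beta_size * dT,
                         config$within_sd_log2)
    ratio <- exp(stats::rnorm(m, log(1.4), 0.15))
    g <- 2^size
    clade <- pool$clade[sp_idx]
    out[[i]] <- data.frame(
      specimen_id = sprintf("%s-%04d", levels$sample_id[i], seq_len(m)),
      sample_id = levels$sample_id[i],
      strat_height = levels$strat_height[i],
      taxon = pool$taxon[sp_idx],
      clade = clade,
      valve = ifelse(clade == "bivalve", "articulated", "ventral"),
      dim_a = g * sqrt(ratio),
      dim_b = g / sqrt(ratio),
      measured = TRUE,
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec$size_log2 <- NA_real_
  rec$provenance <- NA_character_
  list(records = rec, pool = pool)
}

#' Hide the measurements of a subset of specimens
#'
#' Clears the `measured` flag and the dimensions of a random subset of
#' records, emulating fragmentary specimens whose size must be imputed.
#' Under the default completely-at-random, exact-count mode exactly
#' `round(fraction * n)` records are hidden; `missing_size_bias` tilts the
#' selection odds by specimen size for robustness studies. When possible, at
#' least one measured specimen per species is retained (a hidden record is
#' swapped back for a measured conspecific of a species that would otherwise
#' lose all its measurements).
#'
#' @param records Specimen data frame with dimensions present.
#' @param fraction Fraction to hide, in \[0, 1).
#' @param seed Optional seed for the masking draw.
#' @param mode `"exact"` or `"binomial"`.
#' @param size_bias Log-odds of hiding per log2-unit of size (default 0).
#' @return Records with hidden rows set to `measured = FALSE` and `NA`
#'   dimensions.
#' @export
apply_missingness <- function(records, fraction, seed = NULL,
                              mode = c("exact", "binomial"), size_bias = 0) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (fraction == 0 || n == 0) return(records)
  size <- log2(sqrt(records$dim_a * records$dim_b))
  logit <- size_bias * (size - mean(size)) +
    log(fraction / (1 - fraction))
  prob <- 1 / (1 + exp(-logit))
  if (mode == "exact") {
    k <- round(fraction * n)
    hide <- sample.int(n, size = k, prob = prob)
  } else {
    hide <- which(stats::runif(n) < prob)
  }
  hidden <- logical(n); hidden[hide] <- TRUE
  ## keep at least one measured specimen per species when possible
  for (sp in unique(records$taxon)) {
    rows <- which(records$taxon == sp)
    if (length(rows) && all(hidden[rows])) {
      keep <- rows[sample.int(length(rows), 1)]
      hidden[keep] <- FALSE
      ## preserve the exact count by hiding a spare specimen elsewhere
      spare <- which(!hidden & records$taxon != sp)
      cnt <- stats::ave(rep(1L, length(spare)), records$taxon[spare],
                        FUN = sum)
      spare <- spare[cnt > 1]
      if (mode == "exact" && length(spare))
        hidden[spare[sample.int(length(spare), 1)]] <- TRUE
    }
  }
  records$measured[hidden] <- FALSE
  records$dim_a[hidden] <- NA_real_
  records$dim_b[hidden] <- NA_real_
  records
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates [simulate_isotopes()], [simulate_community()] and
#' [apply_missingness()] under a single seed. Regenerating with the same
#' configuration (including seed) is bit-identical.
#'
#' @param config A [simulation_config()].
#' @param params Thermometer parameters.
#' @return A `synthetic_dataset` list: `specimens`, `isotopes`, `levels`,
#'   and `truth` (per-level temperature, species pool with generating sizes,
#'   the betas and the full config).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             params = thermometer_params()) {
  iso <- simulate_isotopes(config, params)   # seeds the RNG stream
  com <- simulate_community(config, iso$truth$temperature, iso$levels)
  spec <- apply_missingness(com$records, config$missing_fraction,
                            mode = config$missing_mode,
                            size_bias = config$missing_size_bias)
  structure(list(
    specimens = spec,
    isotopes = iso$measurements,
    levels = iso$levels,
    truth = list(levels = iso$truth, pool = com$pool,
                 beta_abund = config$beta_abund, beta_size = config$beta_size,
                 config = config)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d specimens over %d levels, %d isotope measurements>\n",
    nrow(x$specimens), nrow(x$levels), nrow(x$isotopes)))
  invisible(x)
}
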