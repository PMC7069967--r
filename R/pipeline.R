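default_run_config <- function() {
  list(
    seed = NULL,
    simulate = NULL,   # simulation_config() fields; NULL when reading files
    input = NULL,      # list(specimens=, isotopes=, levels=) of CSV paths
    analysis = list(groups = c("all", "bivalves", "brachiopods"),
                    lags = c(0, 1), min_per_level = 3, min_levels = 3,
                    common_rule = "strict", alpha = 0.05),
    thermometer = list(d18O_seawater = -1.0, mg_term = 0.0),
    screening = list(mn_max = 0.1, fe_max = 1.0)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Run configurations are declarative YAML files with sections `simulate`
#' (generator parameters, see [simulation_config()]) or `input` (paths to
#' `specimens`/`isotopes`/`levels` CSVs), plus `analysis`, `thermometer`,
#' `screening` and a top-level `seed`. Unspecified fields take package
#' defaults; the fully resolved configuration is written next to every run's
#' outputs.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg
}

normalize_config <- function(config) {
  if (is.character(config)) return(load_run_config(config))
  if (is.null(config)) return(default_run_config())
  merge_config(default_run_config(), config)
}

resolve_sim_config <- function(cfg) {
  args <- cfg$simulate
  if (is.null(args)) args <- list()
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  bad <- setdiff(names(args), names(formals(simulation_config)))
  if (length(bad))
    stop(sprintf("unknown simulation field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.null(args$excursion)) args$excursion <- as.numeric(unlist(args$excursion))
  do.call(simulation_config, args)
}

resolve_thermometer <- function(cfg) {
  args <- cfg$thermometer
  if (is.null(args)) args <- list()
  do.call(thermometer_params, args)
}

#' Simulate a dataset and write it to disk
#'
#' Generates a [simulate_dataset()] under the run configuration and writes
#' `specimens.csv`, `isotopes.csv`, `levels.csv`, the generating truth
#' (`truth_levels.csv`, `truth_species.csv`) and a manifest with the seed and
#' MD5 checksums of every file. Identical configuration and seed reproduce
#' identical files.
#'
#' @param config Configuration list ([load_run_config()]) or a path to a
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  config <- normalize_config(config)
  sim_cfg <- resolve_sim_config(config)
  params <- resolve_thermometer(config)
  ds <- simulate_dataset(sim_cfg, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_specimens(ds$specimens, file.path(out_dir, "specimens.csv"))
  write_isotopes(ds$isotopes, file.path(out_dir, "isotopes.csv"))
  utils::write.csv(ds$levels, file.path(out_dir, "levels.csv"), row.names = FALSE)
  utils::write.csv(ds$truth$levels, file.path(out_dir, "truth_levels.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$truth$pool, file.path(out_dir, "truth_species.csv"),
                   row.names = FALSE)
  files <- c("specimens.csv", "isotopes.csv", "levels.csv",
             "truth_levels.csv", "truth_species.csv")
  manifest <- list(seed = sim_cfg$seed,
                   checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  mf <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

series_on_levels <- function(series, levels) {
  v <- rep(NA_real_, nrow(levels))
  idx <- match(series$sample_id, levels$sample_id)
  v[idx] <- series$value
  v
}

#' Run the full analysis and write report tables
#'
#' Loads (or simulates) a dataset, then executes the complete analysis:
#' rare-group exclusion, size computation and imputation, per-group mean-size
#' trajectories, common-species classification and percent-larger series,
#' isotope screening/aggregation/palaeothermometry, a size ~ percent-larger
#' GLS report per group, and a size-or-percent ~ d18O report at lags 0 and 1
#' per group. Every series and table is written as CSV together with the
#' resolved configuration; pipeline decisions (differencing trigger, selected
#' ARIMA order) are logged.
#'
#' @param config Configuration list or YAML path (see [load_run_config()]).
#' @param out_dir Output directory.
#' @param verbose Log pipeline decisions (default `TRUE`).
#' @return Invisibly, a list with the two report data frames and the series.
#' @export
run_analyze <- function(config = NULL, out_dir, verbose = TRUE) {
  config <- normalize_config(config)
  params <- resolve_thermometer(config)
  an <- config$analysis

  if (!is.null(config$input)) {
    paths <- config$input
    for (p in c(paths$specimens, paths$isotopes))
      if (is.null(p) || !file.exists(p))
        stop(sprintf("[input] unreadable input path: '%s'",
                     if (is.null(p)) "<missing>" else p), call. = FALSE)
    specimens <- read_specimens(paths$specimens)
    isotopes <- read_isotopes(paths$isotopes)
    if (!is.null(paths$levels)) {
      levels <- utils::read.csv(paths$levels, stringsAsFactors = FALSE)
    } else levels <- sample_levels(specimens)
  } else {
    sim_cfg <- resolve_sim_config(config)
    ds <- simulate_dataset(sim_cfg, params)
    specimens <- ds$specimens; isotopes <- ds$isotopes; levels <- ds$levels
  }
  if (is.null(levels$in_event)) levels$in_event <- FALSE

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specimens <- drop_rare_groups(specimens, quiet = !verbose)
  specimens <- impute_sizes(specimens, quiet = !verbose)
  utils::write.csv(levels, file.path(out_dir, "levels.csv"), row.names = FALSE)
  write_specimens(specimens, file.path(out_dir, "specimens_imputed.csv"))

  groups <- an$groups
  size_series <- list()
  for (g in groups) {
    size_series[[g]] <- sample_mean_size(specimens, g)
    write_series(size_series[[g]], file.path(out_dir, paste0("size_", g, ".csv")))
  }

  sp <- common_species(specimens, min_per_level = an$min_per_level,
                       min_levels = an$min_levels, rule = an$common_rule)
  classes <- classify_species_size(specimens, sp)
  cls_out <- classes
  cls_out$cutoff <- attr(classes, "cutoff")
  utils::write.csv(cls_out, file.path(out_dir, "species_classes.csv"),
                   row.names = FALSE)
  pct_series <- list()
  for (g in groups) {
    pct_series[[g]] <- tryCatch(percent_larger(specimens, classes, g),
                                error = function(e) NULL)
    if (!is.null(pct_series[[g]]))
      write_series(pct_series[[g]], file.path(out_dir, paste0("pct_larger_", g, ".csv")))
  }

  isotopes <- screen_measurements(isotopes, mn_max = config$screening$mn_max,
                                  fe_max = config$screening$fe_max)
  iso <- aggregate_isotopes(isotopes, levels, params)
  utils::write.csv(as.data.frame(iso), file.path(out_dir, "isotope_series.csv"),
                   row.names = FALSE)

  pc <- pipeline_config(alpha = an$alpha)
  on_lv <- function(s) if (is.null(s)) rep(NA_real_, nrow(levels))
                       else series_on_levels(s, levels)
  d18O <- {
    v <- rep(NA_real_, nrow(levels))
    v[match(iso$sample_id, levels$sample_id)] <- iso$d18O_mean
    v
  }

  ## size ~ percent-larger, one row per group (lag 0)
  t1 <- list()
  for (g in groups) {
    if (is.null(pct_series[[g]])) next
    row <- tryCatch(
      run_correlation_pipeline(on_lv(size_series[[g]]), on_lv(pct_series[[g]]),
                               lag = 0, config = pc, label = g,
                               verbose = verbose),
      error = function(e) { warning(sprintf("size~pct (%s): %s", g,
                                            conditionMessage(e))); NULL })
    t1[[g]] <- row
  }
  table1 <- do.call(rbind, t1)
  if (!is.null(table1))
    utils::write.csv(table1, file.path(out_dir, "table_size_vs_pct.csv"),
                     row.names = FALSE)

  ## size and percent-larger ~ d18O, lags 0 and 1, per group
  t2 <- list()
  for (resp in c("size", "pct_larger")) {
    for (g in groups) {
      s <- if (resp == "size") size_series[[g]] else pct_series[[g]]
      if (is.null(s)) next
      for (lg in an$lags) {
        lab <- sprintf("%s (%s)", resp, g)
        row <- tryCatch(
          run_correlation_pipeline(on_lv(s), d18O, lag = lg, config = pc,
                                   label = lab, verbose = verbose),
          error = function(e) { warning(sprintf("%s lag %d: %s", lab, lg,
                                                conditionMessage(e))); NULL })
        if (!is.null(row)) { row$response <- resp; t2[[length(t2) + 1]] <- row }
      }
    }
  }
  table2 <- do.call(rbind, t2)
  if (!is.null(table2))
    utils::write.csv(table2, file.path(out_dir, "table_vs_d18O.csv"),
                     row.names = FALSE)

  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(list(size_series = size_series, pct_series = pct_series,
                 isotope_series = iso, classes = classes,
                 table_size_vs_pct = table1, table_vs_d18O = table2))
}

#' Summarise an analysis run
#'
#' Reads the CSV outputs of [run_analyze()] and writes a human-readable
#' markdown summary: per-group mean-size change between the event interval
#' and the rest of the section, the larger/smaller classification counts,
#' and the GLS report tables. Every number is re-read from the CSVs; the
#' summary performs no new analysis.
#'
#' @param out_dir Directory holding [run_analyze()] outputs.
#' @param file Summary filename (default `summary.md` inside `out_dir`).
#' @return Path to the summary, invisibly.
#' @export
run_report <- function(out_dir, file = file.path(out_dir, "summary.md")) {
  need <- file.path(out_dir, c("levels.csv", "species_classes.csv"))
  if (!all(file.exists(need)))
    stop(sprintf("analysis outputs not found in '%s'", out_dir), call. = FALSE)
  levels <- utils::read.csv(file.path(out_dir, "levels.csv"),
                            stringsAsFactors = FALSE)
  classes <- utils::read.csv(file.path(out_dir, "species_classes.csv"),
                             stringsAsFactors = FALSE)
  lines <- c("# Analysis summary", "")
  n_larger <- sum(classes$class == "larger")
  n_smaller <- sum(classes$class == "smaller")
  lines <- c(lines, sprintf(
    "Common species: %d (%d larger-sized / %d smaller-sized; cutoff %.3f log2 mm)",
    nrow(classes), n_larger, n_smaller, classes$cutoff[1]), "")
  for (f in list.files(out_dir, pattern = "^size_.*\\.csv$")) {
    s <- utils::read.csv(file.path(out_dir, f), stringsAsFactors = FALSE)
    g <- sub("^size_(.*)\\.csv$", "\\1", f)
    ev <- levels$sample_id[as.logical(levels$in_event)]
    inside <- s$value[s$sample_id %in% ev]
    outside <- s$value[!(s$sample_id %in% ev)]
    if (length(inside) && length(outside))
      lines <- c(lines, sprintf(
        "Mean shell size (%s): %.3f log2 mm in the event interval vs %.3f outside (change %+.3f)",
        g, mean(inside), mean(outside), mean(inside) - mean(outside)))
  }
  lines <- c(lines, "")
  fmt_table <- function(df, title) {
    c(sprintf("## %s", title), "",
      paste(colnames(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(trimws(format(r, digits = 4)),
                                     collapse = " | ")), "")
  }
  f1 <- file.path(out_dir, "table_size_vs_pct.csv")
  if (file.exists(f1))
    lines <- c(lines, fmt_table(utils::read.csv(f1),
                                "GLS: mean size ~ percent larger-sized"))
  f2 <- file.path(out_dir, "table_vs_d18O.csv")
  if (file.exists(f2))
    lines <- c(lines, fmt_table(utils::read.csv(f2),
                                "GLS: size / percent larger-sized ~ d18O"))
  writeLines(lines, file)
  invisible(file)
}
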