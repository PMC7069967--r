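group_filter <- function(records, group = c("all", "bivalves", "brachiopods")) {
  group <- match.arg(group)
  switch(group,
         all = records,
         bivalves = records[records$clade == "bivalve", , drop = FALSE],
         ## brachiopod subcommunity statistics are restricted to articulate
         ## brachiopods; all brachiopod records in this schema are articulate
         brachiopods = records[records$clade == "brachiopod", , drop = FALSE])
}

new_sample_series <- function(df, statistic) {
  rownames(df) <- NULL
  structure(df, class = c("sample_series", "data.frame"), statistic = statistic)
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series: %s, %d levels>\n", attr(x, "statistic"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-sample mean shell size trajectory
#'
#' Computes, for each sampled level in stratigraphic order, the arithmetic
#' mean of `size_log2` over retained individuals of the chosen group, with
#' the first and third quartiles (interquartile range of the per-level size
#' distribution) and the individual count. Levels with no qualifying
#' specimens are omitted.
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param records Imputed specimen data frame (see [impute_sizes()]).
#' @param group `"all"`, `"bivalves"` or `"brachiopods"` (articulates).
#' @return A `sample_series` data frame:
#'   `sample_id,strat_height,value,q1,q3,n`, ordered by `strat_height`.
#' @export
sample_mean_size <- function(records, group = c("all", "bivalves", "brachiopods")) {
  group <- match.arg(group)
  rec <- group_filter(retained_records(records), group)
  if (!nrow(rec)) stop(sprintf("no retained records for group '%s'", group),
                       call. = FALSE)
  lv <- sample_levels(rec)
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    s <- rec$size_log2[rec$sample_id == lv$sample_id[i]]
    q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(sample_id = lv$sample_id[i], strat_height = lv$strat_height[i],
               value = mean(s), q1 = q[1], q3 = q[2], n = length(s),
               stringsAsFactors = FALSE)
  })
  new_sample_series(do.call(rbind, rows), "mean_size_log2")
}

#' Three-point moving average of a sample series
#'
#' Centred three-point mean used for display smoothing of trajectories. At
#' the endpoints the window shrinks to the available two points, so the
#' series keeps its length. Smoothing is display-only; no analysis consumes
#' the smoothed values.
#'
#' @param series A `sample_series` (or data frame with a `value` column).
#' @return The series with `value` replaced by its smoothed version.
#' @export
moving_average_3 <- function(series) {
  v <- series$value
  n <- length(v)
  if (n == 0) stop("empty series", call. = FALSE)
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 1):min(n, i + 1)
    mean(v[w])
  }, numeric(1))
  series$value <- sm
  series
}

#' Identify common species
#'
#' The size-class and relative-abundance analyses are restricted to common
#' species. Under the default `"strict"` reading, a species is common when it
#' has at least `min_per_level` specimens in each of at least `min_levels`
#' distinct samples (levels with fewer specimens do not count towards
#' `min_levels`). The `"lenient"` reading counts any occupied level towards
#' `min_levels` and requires at least one level with `min_per_level`
#' specimens; both readings are exposed because the phrase "at least three
#' specimens per level and at at least three sampling levels" admits either.
#'
#' @param records Imputed specimen data frame; only retained records count.
#' @param min_per_level Minimum specimens per qualifying level (default 3).
#' @param min_levels Minimum number of qualifying levels (default 3).
#' @param rule `"strict"` (default) or `"lenient"`; see Details.
#' @return Character vector of common species names (possibly empty).
#' @export
common_species <- function(records, min_per_level = 3, min_levels = 3,
                           rule = c("strict", "lenient")) {
  rule <- match.arg(rule)
  rec <- retained_records(records)
  if (!nrow(rec)) return(character())
  counts <- table(rec$taxon, rec$sample_id)
  if (rule == "strict") {
    ok <- rowSums(counts >= min_per_level) >= min_levels
  } else {
    ok <- rowSums(counts >= 1) >= min_levels &
      rowSums(counts >= min_per_level) >= 1
  }
  sort(rownames(counts)[ok])
}

#' Classify common species as larger- or smaller-sized
#'
#' Each common species is summarised by the mean `size_log2` of all its
#' retained specimens; the cutoff is the unweighted global mean of these
#' species means. A species is `larger` when its mean strictly exceeds the
#' cutoff, otherwise `smaller` (ties, measure-zero on continuous data, fall
#' to `smaller` for determinism).
#'
#' @param records Imputed specimen data frame.
#' @param species Character vector of common species (see [common_species()]).
#' @return Data frame `taxon,clade,mean_size,class` with attribute `cutoff`.
#' @export
classify_species_size <- function(records, species) {
  if (length(species) < 2)
    stop("need at least 2 common species for a meaningful cutoff", call. = FALSE)
  rec <- retained_records(records)
  rec <- rec[rec$taxon %in% species, , drop = FALSE]
  means <- tapply(rec$size_log2, rec$taxon, mean)
  clades <- tapply(rec$clade, rec$taxon, function(x) x[1])
  means <- means[species]; clades <- clades[species]
  cutoff <- mean(means)
  out <- data.frame(taxon = species, clade = as.character(clades),
                    mean_size = as.numeric(means),
                    class = ifelse(means > cutoff, "larger", "smaller"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Percent of larger-sized individuals per sample
#'
#' For each level, the number of individuals belonging to larger-class common
#' species as a percentage of all individuals of common species in that
#' level. Levels without any common-species individuals are omitted. This is
#' the composition-change statistic: community mean-size declines driven by
#' species replacement show up as drops in this percentage.
#'
#' @param records Imputed specimen data frame.
#' @param classes Size-class table from [classify_species_size()].
#' @param group `"all"`, `"bivalves"` or `"brachiopods"`.
#' @return A `sample_series` with `value` = percent larger-sized (0-100),
#'   `n` = common-species individuals per level; `q1`/`q3` are `NA` (no
#'   within-level spread is defined for a percentage).
#' @export
percent_larger <- function(records, classes,
                           group = c("all", "bivalves", "brachiopods")) {
  group <- match.arg(group)
  rec <- group_filter(retained_records(records), group)
  rec <- rec[rec$taxon %in% classes$taxon, , drop = FALSE]
  if (!nrow(rec))
    stop(sprintf("no common-species individuals in group '%s'", group),
         call. = FALSE)
  larger <- classes$taxon[classes$class == "larger"]
  lv <- sample_levels(rec)
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    sub <- rec[rec$sample_id == lv$sample_id[i], , drop = FALSE]
    data.frame(sample_id = lv$sample_id[i], strat_height = lv$strat_height[i],
               value = 100 * mean(sub$taxon %in% larger),
               q1 = NA_real_, q3 = NA_real_, n = nrow(sub),
               stringsAsFactors = FALSE)
  })
  new_sample_series(do.call(rbind, rows), "pct_larger")
}

#' Write a sample series to CSV
#'
#' @param series A `sample_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, na = "")
  invisible(path)
}
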