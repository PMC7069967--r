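#' Geometric-mean shell size from two linear dimensions
#'
#' Shell size of a specimen is summarised by the geometric mean of two
#' dimensions: length x width for brachiopods and length x height for
#' bivalves. The result lies between the two input dimensions.
#'
#' @param dim_a,dim_b Linear shell dimensions in mm; both must be positive.
#'   Vectorised.
#' @return Geometric mean `sqrt(dim_a * dim_b)` in mm.
#' @examples
#' geometric_mean_size(16, 9)   # 12
#' @export
geometric_mean_size <- function(dim_a, dim_b) {
  if (any(!is.finite(dim_a)) || any(!is.finite(dim_b)) ||
      any(dim_a <= 0) || any(dim_b <= 0))
    stop("dimensions must be finite and > 0", call. = FALSE)
  sqrt(dim_a * dim_b)
}

#' Log2 shell size
#'
#' All community statistics operate on the base-2 logarithm of the
#' geometric-mean size, so that one unit corresponds to a doubling in
#' linear dimension.
#'
#' @param geomean Geometric-mean size in mm; must be positive. Vectorised.
#' @return log2 size (log2 mm).
#' @export
log2_size <- function(geomean) {
  if (any(!is.finite(geomean)) || any(geomean <= 0))
    stop("geometric mean must be finite and > 0", call. = FALSE)
  log2(geomean)
}

#' Compute log2 sizes for measured specimens
#'
#' Fills `size_log2` for all `measured` rows from their dimensions and marks
#' them with provenance `"measured"`. Unmeasured rows are left untouched for
#' [impute_sizes()].
#'
#' @param records Specimen data frame.
#' @return Records with `size_log2`/`provenance` set on measured rows.
#' @export
compute_sizes <- function(records) {
  m <- which(records$measured)
  if (length(m)) {
    records$size_log2[m] <- log2_size(
      geometric_mean_size(records$dim_a[m], records$dim_b[m]))
    records$provenance[m] <- "measured"
  }
  records
}

#' Hierarchical size imputation for unmeasured specimens
#'
#' Community-level size statistics require a size for every retained
#' individual, including fragmentary specimens that could not be measured.
#' Each unmeasured specimen receives, in priority order:
#'
#' 1. `imputed_same_sample`: the mean `size_log2` of measured conspecifics in
#'    the same sample;
#' 2. `imputed_adjacent`: the mean of the per-sample mean sizes of the species
#'    in the nearest sampled level below and the nearest above that contain
#'    measured conspecifics (one side alone if only one side exists);
#' 3. `dropped`: no measured conspecific anywhere; the record is excluded
#'    from downstream analyses.
#'
#' Means are arithmetic means on the log2 scale, consistent with the scale on
#' which all downstream statistics are computed. Neighbour means in step 2
#' are averaged with equal weight regardless of the number of specimens
#' behind each. Measured values are never altered.
#'
#' @param records Specimen data frame with measured sizes already computed
#'   (see [compute_sizes()]; called automatically if provenance is absent).
#' @param levels Optional level table from [sample_levels()]; derived from
#'   `records` when omitted.
#' @param quiet Suppress the per-provenance count message.
#' @return Records with `size_log2` and `provenance` filled; attribute
#'   `provenance_counts` holds the tally.
#' @export
impute_sizes <- function(records, levels = NULL, quiet = FALSE) {
  if (all(is.na(records$provenance))) records <- compute_sizes(records)
  if (is.null(levels)) levels <- sample_levels(records)
  rank_of <- stats::setNames(seq_len(nrow(levels)), levels$sample_id)
  unknown <- setdiff(unique(records$sample_id), levels$sample_id)
  if (length(unknown))
    stop(sprintf("sample '%s' absent from level table", unknown[1]), call. = FALSE)

  meas <- records[records$measured, c("taxon", "sample_id", "size_log2")]
  ## per species x sample mean of measured sizes, and the level rank of each
  if (nrow(meas)) {
    mean_tab <- stats::aggregate(size_log2 ~ taxon + sample_id, data = meas,
                                 FUN = mean)
    names(mean_tab)[names(mean_tab) == "size_log2"] <- "mean"
  } else {
    mean_tab <- data.frame(taxon = character(), sample_id = character(),
                           mean = numeric(), stringsAsFactors = FALSE)
  }
  mean_tab$rank <- rank_of[mean_tab$sample_id]

  todo <- which(!records$measured)
  for (i in todo) {
    sp <- records$taxon[i]
    rk <- rank_of[[records$sample_id[i]]]
    rows <- mean_tab[mean_tab$taxon == sp, , drop = FALSE]
    same <- rows$mean[rows$rank == rk]
    if (length(same)) {
      records$size_log2[i] <- same
      records$provenance[i] <- "imputed_same_sample"
      next
    }
    below <- rows[rows$rank < rk, , drop = FALSE]
    above <- rows[rows$rank > rk, , drop = FALSE]
    nb <- c(
      if (nrow(below)) below$mean[which.max(below$rank)],
      if (nrow(above)) above$mean[which.min(above$rank)])
    if (length(nb)) {
      records$size_log2[i] <- mean(nb)
      records$provenance[i] <- "imputed_adjacent"
    } else {
      records$size_log2[i] <- NA_real_
      records$provenance[i] <- "dropped"
    }
  }
  counts <- table(factor(records$provenance,
                         levels = c("measured", "imputed_same_sample",
                                    "imputed_adjacent", "dropped")))
  if (!quiet)
    message(sprintf(
      "impute_sizes: %d measured, %d same-sample, %d adjacent, %d dropped",
      counts[["measured"]], counts[["imputed_same_sample"]],
      counts[["imputed_adjacent"]], counts[["dropped"]]))
  attr(records, "provenance_counts") <- counts
  records
}

#' Retained records after imputation
#'
#' @param records Imputed specimen data frame.
#' @return Records with a usable size (provenance other than `dropped`).
#' @export
retained_records <- function(records) {
  out <- records[!is.na(records$provenance) & records$provenance != "dropped", ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of retained specimens whose size was imputed
#'
#' @param records Imputed specimen data frame.
#' @return Proportion in \[0, 1\]: imputed (same-sample or adjacent) over all
#'   retained records.
#' @export
imputed_fraction <- function(records) {
  ret <- retained_records(records)
  if (!nrow(ret)) stop("no retained records; imputed fraction undefined", call. = FALSE)
  mean(ret$provenance %in% c("imputed_same_sample", "imputed_adjacent"))
}
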