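#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for specimen records. Gastropods and corals are
## carried through parsing so that drop_rare_groups() can report what it
## removed; all downstream statistics operate on bivalves and brachiopods.
CLADES <- c("bivalve", "brachiopod", "gastropod", "coral")
VALVES <- c("left", "right", "dorsal", "ventral", "articulated", "unknown")
SUBSTRATES <- c("rhynchonellid", "oyster")

SPECIMEN_COLS <- c("specimen_id", "sample_id", "strat_height", "taxon",
                   "clade", "valve", "dim_a", "dim_b", "measured")
ISOTOPE_COLS <- c("sample_id", "substrate", "d18O", "d13C")

stop_schema <- function(missing, path) {
  stop(sprintf("schema error in '%s': missing mandatory column(s): %s",
               path, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a specimen occurrence table
#'
#' Parses a comma-separated specimen table (UTF-8, `.` decimal separator,
#' header mandatory) into a validated occurrence data frame. Each row is one
#' shell occurrence: a sampled individual with its stratigraphic level, taxon,
#' clade, valve type and two linear dimensions in mm (`dim_a` = length L;
#' `dim_b` = width W for brachiopods, height H for bivalves). The `measured`
#' flag separates directly measured specimens from those whose size must be
#' imputed (see [impute_sizes()]).
#'
#' Validation enforces: all mandatory columns present; clades drawn from
#' bivalve/brachiopod/gastropod/coral; measured rows carry two positive,
#' numeric dimensions; and all rows of a sample share one stratigraphic
#' height. Row order is preserved.
#'
#' @param path Path to a CSV file with header
#'   `specimen_id,sample_id,strat_height,taxon,clade,valve,dim_a,dim_b,measured`.
#' @return A `data.frame` of specimen records with typed columns, plus empty
#'   `size_log2` and `provenance` columns to be filled by the size pipeline.
#' @seealso [write_specimens()], [drop_rare_groups()], [impute_sizes()]
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(SPECIMEN_COLS, names(raw))
  if (length(missing)) stop_schema(missing, path)
  as_specimens(raw, source = path)
}

#' Coerce a raw table to a validated specimen data frame
#'
#' Applies the same typing and validation as [read_specimens()] to an
#' in-memory data frame (e.g. one assembled by the synthetic-data generator
#' or mapped from an external repository schema).
#'
#' @param raw Data frame containing at least the mandatory specimen columns.
#' @param source Label used in error messages.
#' @return Validated specimen data frame.
#' @export
as_specimens <- function(raw, source = "<data.frame>") {
  missing <- setdiff(SPECIMEN_COLS, names(raw))
  if (length(missing)) stop_schema(missing, source)
  n <- nrow(raw)
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    specimen_id  = as.character(raw$specimen_id),
    sample_id    = as.character(raw$sample_id),
    strat_height = num_or_na(as.character(raw$strat_height)),
    taxon        = as.character(raw$taxon),
    clade        = as.character(raw$clade),
    valve        = as.character(raw$valve),
    dim_a        = num_or_na(as.character(raw$dim_a)),
    dim_b        = num_or_na(as.character(raw$dim_b)),
    measured     = parse_logical(raw$measured),
    stringsAsFactors = FALSE
  )
  bad_clade <- !(rec$clade %in% CLADES)
  if (any(bad_clade)) {
    stop(sprintf("unknown clade '%s' at row %d (allowed: %s)",
                 rec$clade[which(bad_clade)[1]], which(bad_clade)[1],
                 paste(CLADES, collapse = ", ")), call. = FALSE)
  }
  bad_valve <- !(rec$valve %in% VALVES)
  if (any(bad_valve)) {
    stop(sprintf("unknown valve '%s' at row %d", rec$valve[which(bad_valve)[1]],
                 which(bad_valve)[1]), call. = FALSE)
  }
  if (anyNA(rec$strat_height)) {
    stop(sprintf("non-numeric strat_height at row %d",
                 which(is.na(rec$strat_height))[1]), call. = FALSE)
  }
  bad_dim <- rec$measured &
    (is.na(rec$dim_a) | is.na(rec$dim_b) | rec$dim_a <= 0 | rec$dim_b <= 0)
  if (any(bad_dim)) {
    stop(sprintf(
      "row %d: measured specimen without two positive numeric dimensions",
      which(bad_dim)[1]), call. = FALSE)
  }
  check_height_consistency(rec)
  if (is.null(raw$size_log2)) rec$size_log2 <- NA_real_
  else rec$size_log2 <- num_or_na(as.character(raw$size_log2))
  if (is.null(raw$provenance)) rec$provenance <- NA_character_
  else {
    prov <- as.character(raw$provenance)
    prov[!nzchar(trimws(prov))] <- NA_character_  # CSV blanks are "not set"
    rec$provenance <- prov
  }
  rec
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop(sprintf("row %d: cannot parse '%s' as logical",
                 which(is.na(out))[1], x[which(is.na(out))[1]]), call. = FALSE)
  }
  out
}

check_height_consistency <- function(rec) {
  byid <- tapply(rec$strat_height, rec$sample_id, function(h) length(unique(h)))
  if (any(byid > 1)) {
    stop(sprintf("sample '%s' carries more than one strat_height",
                 names(byid)[which(byid > 1)[1]]), call. = FALSE)
  }
  invisible(rec)
}

#' Write specimen records to CSV
#'
#' Inverse of [read_specimens()]; a write/read round trip is lossless for all
#' typed fields. `size_log2` and `provenance` columns are included when
#' present so that imputed datasets can be archived.
#'
#' @param records Specimen data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read an isotope measurement table
#'
#' Parses per-specimen stable-isotope and element/Ca data. `d18O` and `d13C`
#' are in permil V-PDB; `mn_ca` and `fe_ca` (mmol/mol) are optional columns
#' used by the diagenesis screen ([screen_measurements()]) and may be absent
#' when screening was applied upstream.
#'
#' @param path Path to a CSV with header
#'   `sample_id,substrate,d18O,d13C,mn_ca,fe_ca` (last two optional).
#' @return Data frame of isotope measurements with an `accepted` column
#'   (all `TRUE` until screened).
#' @export
read_isotopes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(ISOTOPE_COLS, names(raw))
  if (length(missing)) stop_schema(missing, path)
  as_isotopes(raw, source = path)
}

#' Coerce a raw table to a validated isotope data frame
#'
#' @param raw Data frame with at least `sample_id,substrate,d18O,d13C`.
#' @param source Label used in error messages.
#' @return Validated isotope measurement data frame.
#' @export
as_isotopes <- function(raw, source = "<data.frame>") {
  missing <- setdiff(ISOTOPE_COLS, names(raw))
  if (length(missing)) stop_schema(missing, source)
  num_or_na <- function(x) {
    if (is.null(x)) return(rep(NA_real_, nrow(raw)))
    x <- as.character(x)
    x[!nzchar(trimws(x))] <- NA
    suppressWarnings(as.numeric(x))
  }
  rec <- data.frame(
    sample_id = as.character(raw$sample_id),
    substrate = as.character(raw$substrate),
    d18O      = num_or_na(raw$d18O),
    d13C      = num_or_na(raw$d13C),
    mn_ca     = num_or_na(raw$mn_ca),
    fe_ca     = num_or_na(raw$fe_ca),
    stringsAsFactors = FALSE
  )
  bad_sub <- !(rec$substrate %in% SUBSTRATES)
  if (any(bad_sub)) {
    stop(sprintf("unknown substrate '%s' at row %d (allowed: %s)",
                 rec$substrate[which(bad_sub)[1]], which(bad_sub)[1],
                 paste(SUBSTRATES, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(rec$d18O)) {
    stop(sprintf("row %d: non-numeric or missing d18O",
                 which(is.na(rec$d18O))[1]), call. = FALSE)
  }
  if (!is.null(raw$accepted)) rec$accepted <- parse_logical(raw$accepted)
  else rec$accepted <- TRUE
  rec
}

#' Write isotope measurements to CSV
#'
#' @param records Isotope measurement data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotopes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Restrict records to bivalves and brachiopods
#'
#' Gastropods and corals are typically too rare and fragmented in benthic
#' shell assemblages to support quantitative size analysis; this filter
#' removes them and reports the count of excluded records as the
#' `"removed"` attribute (and a message).
#'
#' @param records Specimen data frame.
#' @param quiet Suppress the message.
#' @return Filtered specimen data frame with attribute `removed`.
#' @export
drop_rare_groups <- function(records, quiet = FALSE) {
  keep <- records$clade %in% c("bivalve", "brachiopod")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- sum(!keep)
  if (!quiet && removed > 0)
    message(sprintf("drop_rare_groups: removed %d gastropod/coral record(s)", removed))
  attr(out, "removed") <- removed
  out
}

#' Build the ordered table of sampled levels
#'
#' Derives the unique sampled levels from specimen records and orders them by
#' stratigraphic height, which defines the time axis of all series. Ties in
#' height across distinct sample ids are rejected because they would make the
#' series order ambiguous.
#'
#' @param records Specimen data frame.
#' @param in_event Optional character vector of sample ids falling inside the
#'   chemostratigraphically defined excursion interval.
#' @return Data frame `sample_id,strat_height,in_event` sorted by height, one
#'   row per level.
#' @export
sample_levels <- function(records, in_event = character()) {
  check_height_consistency(records)
  lv <- unique(records[, c("sample_id", "strat_height")])
  if (anyDuplicated(lv$strat_height)) {
    h <- lv$strat_height[duplicated(lv$strat_height)][1]
    stop(sprintf("distinct samples share strat_height %g; series order undefined", h),
         call. = FALSE)
  }
  lv <- lv[order(lv$strat_height), , drop = FALSE]
  rownames(lv) <- NULL
  lv$in_event <- lv$sample_id %in% in_event
  lv
}
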