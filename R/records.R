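#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used across the package. Series-level regions and
## study-level aliases are deliberately distinct enums: monitoring systems
## label individual irradiation events (series) with a finer vocabulary than
## the exam-level grouping used for cohort statistics.
SERIES_REGIONS <- c("head", "neck", "chest", "abdomen_pelvis", "trunk", "undefined")
STUDY_ALIASES <- c("head", "neck", "chest", "abdomen", "pelvis", "undefined")
SCANNER_IDS <- c("CT1", "CT2", "other")
ACQUISITION_TYPES <- c("scout", "axial", "helical", "bolus_tracking")
PHANTOMS <- c("head16", "body32")

SERIES_COLUMNS <- c("study_id", "series_uid", "scanner_id", "protocol_name",
                    "series_region", "acquisition_type", "ctdi_vol", "phantom",
                    "dlp", "scan_length", "d_eff", "d_water")
STUDY_COLUMNS <- c("study_id", "patient_age", "patient_sex", "patient_weight",
                   "study_alias")

ctda_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "ctda_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct a CT dose cohort
#'
#' A cohort bundles a study-level table (one row per CT exam: patient age,
#' sex, weight, study alias) with a series-level table (one row per
#' irradiation event: CTDIvol, DLP, scan length, geometry, region label).
#' Series row order within a study reflects acquisition order; "last series"
#' semantics used elsewhere follow this order.
#'
#' @param studies data.frame with columns `study_id`, `patient_age`,
#'   `patient_sex` (`F`/`M`/`unknown`), `patient_weight` (kg, `NA` allowed),
#'   `study_alias`.
#' @param series data.frame with columns `study_id`, `series_uid`,
#'   `scanner_id`, `protocol_name`, `series_region`, `acquisition_type`,
#'   `ctdi_vol` (mGy), `phantom`, `dlp` (mGy·cm), `scan_length` (cm), and
#'   optional `d_eff`, `d_water` (cm, `NA` allowed).
#' @return An object of class `ct_cohort`.
#' @export
ct_cohort <- function(studies, series) {
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  series <- as.data.frame(series, stringsAsFactors = FALSE)
  for (col in setdiff(c("d_eff", "d_water"), names(series))) series[[col]] <- NA_real_
  missing_s <- setdiff(STUDY_COLUMNS, names(studies))
  missing_r <- setdiff(SERIES_COLUMNS, names(series))
  if (length(missing_s) || length(missing_r)) {
    ctda_error("ctda_schema_error", "missing column(s): %s",
               paste(c(missing_s, missing_r), collapse = ", "))
  }
  studies <- studies[STUDY_COLUMNS]
  series <- series[SERIES_COLUMNS]
  validate_cohort(studies, series)
  structure(list(studies = studies, series = series), class = "ct_cohort")
}

validate_cohort <- function(studies, series) {
  if (anyDuplicated(studies$study_id)) {
    ctda_error("ctda_validation_error", "duplicate study_id: %s",
               studies$study_id[duplicated(studies$study_id)][1L])
  }
  if (any(!nzchar(series$series_uid)) || anyNA(series$series_uid)) {
    ctda_error("ctda_validation_error", "empty series_uid")
  }
  if (anyDuplicated(series$series_uid)) {
    ctda_error("ctda_validation_error", "duplicate series_uid: %s",
               series$series_uid[duplicated(series$series_uid)][1L])
  }
  orphans <- setdiff(series$study_id, studies$study_id)
  if (length(orphans)) {
    ctda_error("ctda_validation_error", "series reference unknown study_id: %s",
               orphans[1L])
  }
  num_ok <- function(x, lo, strict = FALSE) {
    x <- x[!is.na(x)]
    if (strict) all(x > lo) else all(x >= lo)
  }
  if (!num_ok(series$ctdi_vol, 0)) ctda_error("ctda_validation_error", "negative ctdi_vol")
  if (!num_ok(series$dlp, 0)) ctda_error("ctda_validation_error", "negative dlp")
  if (!num_ok(series$scan_length, 0)) ctda_error("ctda_validation_error", "negative scan_length")
  if (!num_ok(series$d_eff, 0, strict = TRUE)) {
    ctda_error("ctda_validation_error", "d_eff must be > 0 when present")
  }
  if (!num_ok(studies$patient_age, 0)) ctda_error("ctda_validation_error", "negative patient_age")
  if (!num_ok(studies$patient_weight, 0, strict = TRUE)) {
    ctda_error("ctda_validation_error", "patient_weight must be > 0 when present")
  }
  bad_region <- setdiff(unique(series$series_region), SERIES_REGIONS)
  if (length(bad_region)) {
    ctda_error("ctda_validation_error", "unknown series_region: %s", bad_region[1L])
  }
  invisible(TRUE)
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d studies, %d series\n",
              nrow(x$studies), nrow(x$series)))
  tab <- table(factor(x$studies$study_alias, levels = STUDY_ALIASES))
  cat("study aliases:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of studies in a cohort
#' @param x a `ct_cohort`
#' @export
n_studies <- function(x) nrow(x$studies)

## Normalise free-text region / alias labels to the controlled vocabulary.
## Anything unmapped or blank becomes "undefined" (never an error at ingest).
normalize_label <- function(x, vocabulary) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ +/-]+", "_", x)
  x[x %in% c("abdomen_pelvis", "abdomenpelvis", "abd_pelvis")] <- "abdomen_pelvis"
  x[is.na(x) | !nzchar(x) | !(x %in% vocabulary)] <- "undefined"
  x
}

default_dialect <- function() {
  list(sep = ",", columns = stats::setNames(
    c(SERIES_COLUMNS, STUDY_COLUMNS[-1L]),
    c(SERIES_COLUMNS, STUDY_COLUMNS[-1L])))
}

#' Read a flat per-series dose table
#'
#' Reads a delimited text export (one row per series, study-level fields
#' repeated on each row) into a [ct_cohort]. Column names are mapped through
#' a dialect configuration so exports with arbitrary headers can be ingested
#' without editing the file. Units are taken verbatim: mGy, mGy·cm, cm, kg.
#'
#' @param path path to a delimited text file with a header row (UTF-8).
#' @param dialect optional list with `sep` (field separator) and `columns`, a
#'   named character vector mapping file header names to canonical field
#'   names. Defaults to the identity mapping with comma separation.
#' @return A [ct_cohort]. Blank or unrecognised region labels become
#'   `"undefined"`.
#' @export
read_series_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) ctda_error("ctda_io_error", "file not found: %s", path)
  if (is.null(dialect)) dialect <- default_dialect()
  sep <- if (is.null(dialect$sep)) "," else dialect$sep
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  map <- dialect$columns
  hit <- names(raw) %in% names(map)
  names(raw)[hit] <- unname(map[names(raw)[hit]])
  cohort_from_flat(raw)
}

cohort_from_flat <- function(raw) {
  mandatory <- c("study_id", "series_uid", "scanner_id", "protocol_name",
                 "series_region", "acquisition_type", "ctdi_vol", "phantom",
                 "dlp", "scan_length")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    ctda_error("ctda_schema_error", "missing mandatory column(s): %s",
               paste(missing, collapse = ", "))
  }
  for (col in c("d_eff", "d_water", "patient_age", "patient_sex",
                "patient_weight", "study_alias")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  parse_num <- function(col) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad)) {
      ctda_error("ctda_validation_error",
                 "non-numeric value '%s' in column '%s' at row %d",
                 x[bad[1L]], col, bad[1L])
    }
    out
  }
  for (col in c("ctdi_vol", "dlp", "scan_length", "d_eff", "d_water",
                "patient_age", "patient_weight")) {
    raw[[col]] <- parse_num(col)
  }
  raw$series_region <- normalize_label(raw$series_region, SERIES_REGIONS)
  raw$acquisition_type <- normalize_label(raw$acquisition_type, ACQUISITION_TYPES)
  raw$scanner_id <- ifelse(raw$scanner_id %in% SCANNER_IDS, raw$scanner_id, "other")
  raw$phantom <- normalize_label(raw$phantom, PHANTOMS)
  raw$phantom[raw$phantom == "undefined"] <- "body32"
  sex <- toupper(trimws(raw$patient_sex))
  raw$patient_sex <- ifelse(sex %in% c("F", "M"), sex, "unknown")
  raw$study_alias <- normalize_label(raw$study_alias, STUDY_ALIASES)

  first <- !duplicated(raw$study_id)
  studies <- raw[first, STUDY_COLUMNS]
  rownames(studies) <- NULL
  series <- raw[SERIES_COLUMNS]
  rownames(series) <- NULL
  ct_cohort(studies, series)
}

#' Write a cohort as a flat per-series table
#'
#' Inverse of [read_series_table()]: study-level fields are repeated on each
#' series row. Numeric fields survive a write/read round trip to at least
#' 1e-9 relative precision.
#'
#' @param cohort a [ct_cohort]
#' @param path output file path
#' @param sep field separator (default comma)
#' @export
write_series_table <- function(cohort, path, sep = ",") {
  flat <- merge(cohort$series, cohort$studies, by = "study_id", sort = FALSE)
  ## merge() may reorder; restore acquisition order
  flat <- flat[match(cohort$series$series_uid, flat$series_uid), ]
  flat <- flat[c(SERIES_COLUMNS, STUDY_COLUMNS[-1L])]
  utils::write.table(flat, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Write / read series records as JSON lines
#'
#' One JSON object per line, same flat schema as [write_series_table()].
#' @param cohort a [ct_cohort]
#' @param path output path
#' @rdname series_jsonl
#' @export
write_series_jsonl <- function(cohort, path) {
  flat <- merge(cohort$series, cohort$studies, by = "study_id", sort = FALSE)
  flat <- flat[match(cohort$series$series_uid, flat$series_uid), ]
  flat <- flat[c(SERIES_COLUMNS, STUDY_COLUMNS[-1L])]
  lines <- vapply(seq_len(nrow(flat)), function(i) {
    jsonlite::toJSON(as.list(flat[i, ]), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @param path input path
#' @rdname series_jsonl
#' @export
read_series_jsonl <- function(path) {
  if (!file.exists(path)) ctda_error("ctda_io_error", "file not found: %s", path)
  rows <- lapply(readLines(path), function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  raw <- do.call(rbind, rows)
  for (col in names(raw)) raw[[col]] <- as.character(raw[[col]])
  cohort_from_flat(raw)
}

#' Default cohort exclusion rules
#'
#' Mirrors the audit's cohort definition: exams below a minimum patient age,
#' exams without a usable study alias, extremity and whole-body exams, and
#' protocol-name patterns (clinical trials, poorly written protocol names)
#' are excluded. The age threshold defaults to 16 years, matching a cohort
#' whose youngest included patient is 16.
#'
#' @param min_age minimum included age in years (exclusive lower bound is
#'   `min_age`; `age < min_age` is excluded)
#' @param excluded_aliases study aliases to drop (reason `undefined_region`)
#' @param extremity_pattern,whole_body_pattern,protocol_pattern case-insensitive
#'   regular expressions over protocol names, each mapped to its reason tag
#' @return a list of rules for [filter_cohort()]
#' @export
cohort_filter_rules <- function(min_age = 16,
                                excluded_aliases = "undefined",
                                extremity_pattern = "extremit|wrist|ankle|knee|elbow|hand|foot",
                                whole_body_pattern = "whole[ ._-]?body",
                                protocol_pattern = "clinical[ ._-]?trial|^\\s*$") {
  list(min_age = min_age, excluded_aliases = excluded_aliases,
       extremity_pattern = extremity_pattern,
       whole_body_pattern = whole_body_pattern,
       protocol_pattern = protocol_pattern)
}

#' Partition a cohort into kept and excluded studies
#'
#' Applies the exclusion rules study by study. Every excluded study carries a
#' machine-readable reason tag (`age`, `undefined_region`, `extremity`,
#' `whole_body`, `protocol_pattern`); the first matching rule, in that order,
#' wins. Kept and excluded studies always partition the input.
#'
#' @param cohort a [ct_cohort]
#' @param rules see [cohort_filter_rules()]
#' @return list with `kept` (a [ct_cohort]) and `excluded`
#'   (data.frame `study_id`, `reason`)
#' @export
filter_cohort <- function(cohort, rules = cohort_filter_rules()) {
  studies <- cohort$studies
  reason <- rep(NA_character_, nrow(studies))
  protos <- split(cohort$series$protocol_name, cohort$series$study_id)
  proto_of <- function(id) paste(protos[[id]], collapse = " | ")
  for (i in seq_len(nrow(studies))) {
    id <- studies$study_id[i]
    p <- proto_of(id)
    if (!is.na(studies$patient_age[i]) && studies$patient_age[i] < rules$min_age) {
      reason[i] <- "age"
    } else if (studies$study_alias[i] %in% rules$excluded_aliases) {
      reason[i] <- "undefined_region"
    } else if (grepl(rules$extremity_pattern, p, ignore.case = TRUE)) {
      reason[i] <- "extremity"
    } else if (grepl(rules$whole_body_pattern, p, ignore.case = TRUE)) {
      reason[i] <- "whole_body"
    } else if (grepl(rules$protocol_pattern, p, ignore.case = TRUE)) {
      reason[i] <- "protocol_pattern"
    }
  }
  drop <- !is.na(reason)
  kept_ids <- studies$study_id[!drop]
  kept <- subset_cohort(cohort, kept_ids)
  excluded <- data.frame(study_id = studies$study_id[drop],
                         reason = reason[drop], stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}

#' Subset a cohort by study id, preserving order
#' @param cohort a [ct_cohort]
#' @param study_ids studies to keep
#' @export
subset_cohort <- function(cohort, study_ids) {
  structure(list(
    studies = cohort$studies[cohort$studies$study_id %in% study_ids, , drop = FALSE],
    series = cohort$series[cohort$series$study_id %in% study_ids, , drop = FALSE]
  ), class = "ct_cohort")
}

#' Match series across two monitoring systems by series UID
#'
#' Pairs records from two views of the same scanners (e.g. a local monitoring
#' system and a commercial one) on the DICOM series instance UID. The three
#' outputs partition the union of the inputs.
#'
#' @param dms,dw series data.frames (or `ct_cohort`s) with a `series_uid`
#'   column, UIDs unique within each input
#' @return list with `pairs` (data.frame of the two views column-merged with
#'   suffixes `.dms` / `.dw`), `unmatched_dms`, `unmatched_dw`
#' @export
match_series <- function(dms, dw) {
  if (inherits(dms, "ct_cohort")) dms <- dms$series
  if (inherits(dw, "ct_cohort")) dw <- dw$series
  for (nm in c("dms", "dw")) {
    uids <- get(nm)$series_uid
    if (anyDuplicated(uids)) {
      ctda_error("ctda_validation_error", "duplicate series_uid in %s input: %s",
                 nm, uids[duplicated(uids)][1L])
    }
  }
  shared <- intersect(dms$series_uid, dw$series_uid)
  pairs <- merge(dms[dms$series_uid %in% shared, , drop = FALSE],
                 dw[dw$series_uid %in% shared, , drop = FALSE],
                 by = "series_uid", suffixes = c(".dms", ".dw"), sort = TRUE)
  list(pairs = pairs,
       unmatched_dms = dms[!dms$series_uid %in% shared, , drop = FALSE],
       unmatched_dw = dw[!dw$series_uid %in% shared, , drop = FALSE])
}

#' Per-alias study counts
#'
#' Bookkeeping summary: counts of studies per study alias. The counts always
#' sum to the cohort's study total.
#' @param cohort a [ct_cohort]
#' @return data.frame with `study_alias`, `n`, plus an attribute `total`
#' @export
alias_counts <- function(cohort) {
  tab <- table(factor(cohort$studies$study_alias, levels = STUDY_ALIASES))
  out <- data.frame(study_alias = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(cohort$studies)
  out
}
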