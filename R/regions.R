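#' Default protocol-to-region keyword rules
#'
#' Ordered keyword rules mapping free-text CT protocol names to the
#' series-region vocabulary; the first matching rule wins, unmatched names
#' fall through to `"undefined"`. Matching is case-insensitive regex. The
#' defaults cover common protocol naming (head/brain/skull, cervical/neck,
#' chest/thorax/HRCT, abdomen/pelvis keywords, trunk/polytrauma) and are
#' fully user-overridable via [alias_rules()].
#'
#' @return an `alias_rules` object
#' @export
default_alias_rules <- function() {
  alias_rules(data.frame(
    pattern = c(
      "polytrauma", "trunk", "chest.*abdomen.*pelvis", "\\bcap\\b",
      "abdomen.*pelvis", "pelvis.*abdomen",
      "abdom|\\babdo\\b|liver|pancrea|kidney|urogra|enterogra",
      "pelvi",
      "head|brain|skull|crani|cerebr|sinus",
      "neck|cervic|carotid|larynx",
      "chest|thorax|hrct|lung|pulmon|\\bpe\\b"
    ),
    alias = c(
      "trunk", "trunk", "trunk", "trunk",
      "abdomen_pelvis", "abdomen_pelvis",
      "abdomen_pelvis",
      "abdomen_pelvis",
      "head",
      "neck",
      "chest"
    ),
    stringsAsFactors = FALSE
  ))
}

#' Build an ordered protocol-classification rule set
#'
#' @param rules data.frame with character columns `pattern` (case-insensitive
#'   regular expression over the protocol name) and `alias` (a series region).
#'   Rule order is significant: the first match wins.
#' @return an `alias_rules` object
#' @export
alias_rules <- function(rules) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (!all(c("pattern", "alias") %in% names(rules)) || nrow(rules) == 0L) {
    ctda_error("ctda_config_error",
               "alias rules need a non-empty data.frame with 'pattern' and 'alias'")
  }
  bad <- setdiff(rules$alias, SERIES_REGIONS)
  if (length(bad)) {
    ctda_error("ctda_config_error", "unknown alias in rule set: %s", bad[1L])
  }
  structure(rules[c("pattern", "alias")], class = c("alias_rules", "data.frame"))
}

#' Read / write alias rules as JSON
#' @param path file path
#' @rdname alias_rules_io
#' @export
read_alias_rules <- function(path) {
  alias_rules(jsonlite::fromJSON(path))
}

#' @param rules an `alias_rules` object
#' @rdname alias_rules_io
#' @export
write_alias_rules <- function(rules, path) {
  jsonlite::write_json(as.data.frame(rules), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Classify a protocol name into a body region
#'
#' Deterministic first-match lookup over an ordered rule set. Vectorised over
#' `protocol_name`.
#'
#' @param protocol_name character vector of free-text protocol names
#' @param rules an [alias_rules()] rule set
#' @return character vector of series regions (`"undefined"` when no rule
#'   matches)
#' @export
classify_protocol <- function(protocol_name, rules = default_alias_rules()) {
  out <- rep("undefined", length(protocol_name))
  undecided <- !is.na(protocol_name) & nzchar(trimws(protocol_name))
  for (i in seq_len(nrow(rules))) {
    if (!any(undecided)) break
    hit <- undecided & grepl(rules$pattern[i], protocol_name,
                             ignore.case = TRUE, perl = TRUE)
    out[hit] <- rules$alias[i]
    undecided <- undecided & !hit
  }
  out
}

#' Derive a study-level alias from series regions
#'
#' Scouts and bolus-tracking series never determine the study alias. If all
#' diagnostic (non-scout, non-bolus) series share one region, that region is
#' the alias; otherwise the study is flagged multi-region and the alias is
#' taken from the series with the largest DLP (dose attribution dominates).
#' Series regions are then mapped into the study-alias vocabulary:
#' `abdomen_pelvis` becomes `abdomen` by default, and `trunk` — which has no
#' study-level counterpart — also maps to `abdomen` unless overridden.
#'
#' @param cohort a [ct_cohort]
#' @param region_map named character vector mapping series regions to study
#'   aliases
#' @return data.frame with `study_id`, `study_alias`, `multi_region`
#' @export
derive_study_alias <- function(cohort,
                               region_map = c(head = "head", neck = "neck",
                                              chest = "chest",
                                              abdomen_pelvis = "abdomen",
                                              trunk = "abdomen",
                                              undefined = "undefined")) {
  per_study <- split(cohort$series, factor(cohort$series$study_id,
                                           levels = unique(cohort$series$study_id)))
  rows <- lapply(per_study, function(s) {
    diag <- s[!s$acquisition_type %in% c("scout", "bolus_tracking"), , drop = FALSE]
    if (nrow(diag) == 0L) {
      ctda_error("ctda_validation_error",
                 "no diagnostic series in study %s", s$study_id[1L])
    }
    regions <- unique(diag$series_region)
    if (length(regions) == 1L) {
      data.frame(study_id = s$study_id[1L],
                 study_alias = unname(region_map[regions]),
                 multi_region = FALSE, stringsAsFactors = FALSE)
    } else {
      dominant <- diag$series_region[which.max(diag$dlp)]
      data.frame(study_id = s$study_id[1L],
                 study_alias = unname(region_map[dominant]),
                 multi_region = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emulate a monitoring system's fixed-region assignment
#'
#' Reproduces the failure mode of commercial dose-monitoring systems that
#' store a single, non-editable body region per study: the region of the last
#' series is propagated to every series of the study. By default the last
#' *diagnostic* series determines the region (scouts and bolus tracking are
#' skipped, falling back to the literal last series for scout-only studies);
#' `last = "any"` uses the literal last stored series instead. The operation
#' is idempotent and leaves single-region studies' labels unchanged.
#'
#' @param cohort a [ct_cohort]; the input is not modified
#' @param last `"diagnostic"` (default) or `"any"` — which series defines the
#'   propagated region
#' @return a copy of `cohort` with rewritten `series_region` labels
#' @export
emulate_fixed_region <- function(cohort, last = c("diagnostic", "any")) {
  last <- match.arg(last)
  if (nrow(cohort$series) == 0L) {
    ctda_error("ctda_validation_error", "cohort has no series")
  }
  series <- cohort$series
  for (id in unique(series$study_id)) {
    idx <- which(series$study_id == id)
    if (!length(idx)) next
    cand <- idx
    if (last == "diagnostic") {
      diag <- idx[!series$acquisition_type[idx] %in% c("scout", "bolus_tracking")]
      if (length(diag)) cand <- diag
    }
    series$series_region[idx] <- series$series_region[cand[length(cand)]]
  }
  structure(list(studies = cohort$studies, series = series), class = "ct_cohort")
}
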