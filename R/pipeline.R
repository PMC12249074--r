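#' Audit run configuration
#'
#' Exactly one input source: either `input` (path to a flat per-series dose
#' table, see [read_series_table()]) or `cohort` (a [cohort_config()] for a
#' synthetic run).
#'
#' @param input optional path to a delimited series table
#' @param cohort optional [cohort_config()]
#' @param rules cohort exclusion rules, see [cohort_filter_rules()]
#' @param dms_factors,dw_factors conversion-factor tables for the two views
#' @param segments reference SED–SSDE segments, see [martin_segments()]
#' @param out_dir output directory for the report bundle
#' @param dialect optional input dialect for [read_series_table()]
#' @return a `run_config` list
#' @export
run_config <- function(input = NULL, cohort = NULL,
                       rules = cohort_filter_rules(),
                       dms_factors = conversion_factors("aapm_rpt96"),
                       dw_factors = conversion_factors("deak2010"),
                       segments = martin_segments(),
                       out_dir = tempfile("ctda_audit_"),
                       dialect = NULL) {
  if (is.null(input) == is.null(cohort)) {
    ctda_error("ctda_config_error",
               "supply exactly one of 'input' (a file path) or 'cohort' (a cohort_config)")
  }
  structure(list(input = input, cohort = cohort, rules = rules,
                 dms_factors = dms_factors, dw_factors = dw_factors,
                 segments = segments, out_dir = out_dir, dialect = dialect),
            class = "run_config")
}

## Map the set of diagnostic series regions of a study onto the segment
## vocabulary used by the SED-SSDE reference regressions.
martin_region_of <- function(regions) {
  regions <- sort(unique(regions))
  key <- paste(regions, collapse = "+")
  switch(key,
         "chest" = "chest",
         "abdomen_pelvis" = "abdomen_pelvis",
         "trunk" = "cap",
         "abdomen_pelvis+chest" = "chest_abdomen",
         NA_character_)
}

#' Run the full dose-monitoring audit
#'
#' End-to-end orchestration: ingest (or generate) the two monitoring-system
#' views, filter the cohort, derive study aliases, compute per-study dose
#' metrics (ED under both factor tables, weight-corrected SED, mean
#' diagnostic SSDE, and SED estimated from SSDE where a calibrated segment
#' applies), build the region/scanner slope-comparison table, and summarise
#' distributions as box statistics. Five artifacts are written to
#' `config$out_dir`: `metrics.csv`, `slope_table.csv`, `slope_table.json`,
#' `box_stats.json`, `exclusions.csv`. Identical configurations produce
#' byte-identical artifacts.
#'
#' @param config a [run_config()]
#' @return (invisibly) the report bundle: `metrics`, `slope_table`,
#'   `box_stats`, `exclusions`, `alias_counts`, `paths`
#' @export
run_audit <- function(config) {
  if (!inherits(config, "run_config")) {
    ctda_error("ctda_config_error", "config must be a run_config()")
  }
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      ctda_error("ctda_io_error", "unreadable input: %s", config$input)
    }
    dms <- read_series_table(config$input, config$dialect)
    dw <- emulate_fixed_region(dms)
  } else {
    gen <- generate_cohort(config$cohort)
    dms <- gen$dms_view
    dw <- gen$dw_view
  }

  filt <- filter_cohort(dms, config$rules)
  kept <- filt$kept
  dw_kept <- subset_cohort(dw, kept$studies$study_id)
  aliases <- derive_study_alias(kept)

  ed_dms <- study_ed_total(kept, config$dms_factors)
  ed_dw <- study_ed_total(dw_kept, config$dw_factors)
  w <- kept$studies$patient_weight
  sed <- rep(NA_real_, nrow(kept$studies))
  has_w <- !is.na(w)
  sed[has_w] <- ed_dms[has_w] * compute_wkg(w[has_w])

  series <- kept$series
  diag <- series$acquisition_type != "scout" & !is.na(series$d_eff)
  series$ssde <- NA_real_
  if (any(diag)) {
    series$ssde[diag] <- mapply(
      function(ctdi, d, ph) ssde_from_deff(ctdi, d, ph),
      series$ctdi_vol[diag], series$d_eff[diag], series$phantom[diag])
  }

  per_study <- split(series[diag, , drop = FALSE],
                     factor(series$study_id[diag],
                            levels = kept$studies$study_id))
  ssde_mean <- vapply(per_study, function(s) {
    if (nrow(s)) mean(s$ssde) else NA_real_
  }, numeric(1))
  scan_len <- vapply(per_study, function(s) sum(s$scan_length), numeric(1))
  mregion <- vapply(per_study, function(s) {
    if (nrow(s)) martin_region_of(s$series_region) else NA_character_
  }, character(1))
  dlp_total <- vapply(split(kept$series$dlp, factor(kept$series$study_id,
                                                    levels = kept$studies$study_id)),
                      sum, numeric(1))

  sed_from_curve <- rep(NA_real_, nrow(kept$studies))
  for (i in seq_along(sed_from_curve)) {
    if (is.na(mregion[i]) || is.na(ssde_mean[i])) next
    sed_from_curve[i] <- tryCatch(
      suppressWarnings(sed_from_ssde(ssde_mean[i], mregion[i], scan_len[i],
                                     config$segments)),
      ctda_range_error = function(e) NA_real_)
  }

  metrics <- data.frame(
    study_id = kept$studies$study_id,
    study_alias = aliases$study_alias,
    multi_region = aliases$multi_region,
    scanner_id = vapply(split(kept$series$scanner_id,
                              factor(kept$series$study_id,
                                     levels = kept$studies$study_id)),
                        function(x) x[1L], character(1)),
    martin_region = unname(mregion),
    dlp_total = unname(dlp_total),
    ed_dms = unname(ed_dms),
    ed_dw = unname(ed_dw),
    sed_dms = unname(sed),
    ssde_mean = unname(ssde_mean),
    scan_length_total = unname(scan_len),
    sed_from_ssde = sed_from_curve,
    stringsAsFactors = FALSE)

  pts <- metrics[!is.na(metrics$martin_region) & !is.na(metrics$ssde_mean) &
                   !is.na(metrics$sed_dms), ]
  points <- data.frame(region = pts$martin_region, scanner_id = pts$scanner_id,
                       ssde = pts$ssde_mean, sed = pts$sed_dms,
                       ed = pts$ed_dms, stringsAsFactors = FALSE)
  slope_table <- build_slope_table(points, config$segments)

  box_stats <- list(ed_dms = unclass(summarize_box(metrics$ed_dms)),
                    ed_dw = unclass(summarize_box(metrics$ed_dw)),
                    sed_dms = if (any(!is.na(metrics$sed_dms)))
                      unclass(summarize_box(metrics$sed_dms)) else NULL,
                    dlp = unclass(summarize_box(metrics$dlp_total)))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    metrics = file.path(config$out_dir, "metrics.csv"),
    slope_csv = file.path(config$out_dir, "slope_table.csv"),
    slope_json = file.path(config$out_dir, "slope_table.json"),
    box = file.path(config$out_dir, "box_stats.json"),
    exclusions = file.path(config$out_dir, "exclusions.csv"))
  utils::write.csv(metrics, paths$metrics, row.names = FALSE, na = "")
  write_slope_table(slope_table, paths$slope_csv, "csv")
  write_slope_table(slope_table, paths$slope_json, "json")
  jsonlite::write_json(box_stats, paths$box, auto_unbox = TRUE, digits = NA)
  utils::write.csv(filt$excluded, paths$exclusions, row.names = FALSE)

  invisible(list(metrics = metrics, slope_table = slope_table,
                 box_stats = box_stats, exclusions = filt$excluded,
                 alias_counts = alias_counts(kept), paths = paths))
}

#' Reference fitted slopes from a published two-scanner audit
#'
#' Region/scanner OLS fits (slope, intercept, R²) of weight-corrected SED
#' against SSDE and of ED against SSDE, as printed by the published
#' dose-monitoring audit this package's worked examples reproduce. Used as
#' *inputs* for the slope percent-difference arithmetic; blanks in the
#' original table (exam types one scanner never ran) are simply absent rows.
#'
#' @return data.frame `region`, `scanner_id`, `metric` (`sed`/`ed`),
#'   `slope`, `intercept`, `r2`
#' @export
reported_fits <- function() {
  path <- system.file("extdata", "reported_fits.csv", package = "ctdoseaudit",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Study-alias counts of the published audit cohort
#'
#' Per-alias study counts of the published cohort the package's defaults are
#' modelled on; their sum is the cohort's exam total.
#' @return data.frame `study_alias`, `n`
#' @export
reported_alias_counts <- function() {
  path <- system.file("extdata", "cohort_alias_counts.csv",
                      package = "ctdoseaudit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
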