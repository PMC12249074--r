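#' Synthetic two-scanner cohort configuration
#'
#' Describes the statistical world the generator emulates: a mixed-region
#' adult CT cohort on two scanners, observed through two monitoring-system
#' views — a region-correct view and a "commercial" view in which every
#' series of a study inherits the region of the last diagnostic series.
#'
#' Defaults encode the audited cohort's stated structure: age truncated
#' normal (mean 63.3 y, sd 15.3 y, bounds 16–104), study-alias mix
#' proportional to the audited study counts (head 22051, neck 1378, chest
#' 40810, abdomen 14541, pelvis 603), scan lengths uniform within the
#' calibrated per-region windows, and DLP = CTDIvol × scan length exactly.
#' Weight (not reported in the source cohort) defaults to a truncated
#' normal, 75 ± 15 kg on [40, 150]; effective diameter is affine in weight
#' for body regions so the SSDE–SED correlation structure the analysis
#' relies on is present by construction.
#'
#' @param n_studies number of studies to generate
#' @param seed integer seed; fully determines the output
#' @param scanner_mix named proportions over `CT1`/`CT2`
#' @param study_alias_mix named proportions over study aliases (normalised)
#' @param age_model,weight_model lists `mean`, `sd`, `lo`, `hi` (truncated
#'   normal)
#' @param deff_model list `slope`, `intercept`, `sd` (body regions, cm vs kg)
#'   and `head_mean`, `head_sd`
#' @param ctdi_model named per-region lognormal medians (mGy) plus `sdlog`
#'   and `scout_median`
#' @param scan_length_windows named list of `c(lo, hi)` cm windows per series
#'   region
#' @param multi_region_prob probability a study acquires a second, different
#'   body region
#' @param misassignment if `TRUE`, the commercial view applies the
#'   fixed-region failure mode
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_studies = 500,
                          seed = 1L,
                          scanner_mix = c(CT1 = 0.5, CT2 = 0.5),
                          study_alias_mix = c(head = 22051, neck = 1378,
                                              chest = 40810, abdomen = 14541,
                                              pelvis = 603) / 79383,
                          age_model = list(mean = 63.3, sd = 15.3,
                                           lo = 16, hi = 104),
                          weight_model = list(mean = 75, sd = 15,
                                              lo = 40, hi = 150),
                          deff_model = list(slope = 0.2, intercept = 14,
                                            sd = 1.5, head_mean = 17,
                                            head_sd = 1),
                          ctdi_model = list(head = 40, neck = 15, chest = 8,
                                            abdomen_pelvis = 12, trunk = 12,
                                            sdlog = 0.25, scout_median = 0.1),
                          scan_length_windows = list(
                            head = c(12, 18), neck = c(15, 25),
                            chest = c(30, 37), abdomen_pelvis = c(40, 50),
                            trunk = c(62, 70)),
                          multi_region_prob = 0.1,
                          misassignment = TRUE) {
  check_mix <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      ctda_error("ctda_config_error", "%s proportions must be >= 0 and sum to 1",
                 what)
    }
  }
  study_alias_mix <- study_alias_mix / sum(study_alias_mix)
  check_mix(scanner_mix, "scanner_mix")
  check_mix(study_alias_mix, "study_alias_mix")
  if (multi_region_prob < 0 || multi_region_prob > 1) {
    ctda_error("ctda_config_error", "multi_region_prob must be in [0, 1]")
  }
  structure(list(n_studies = n_studies, seed = as.integer(seed),
                 scanner_mix = scanner_mix, study_alias_mix = study_alias_mix,
                 age_model = age_model, weight_model = weight_model,
                 deff_model = deff_model, ctdi_model = ctdi_model,
                 scan_length_windows = scan_length_windows,
                 multi_region_prob = multi_region_prob,
                 misassignment = isTRUE(misassignment)),
            class = "cohort_config")
}

## Truncated normal by rejection; n is small per study so this is cheap.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n * 2 + 10, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

ALIAS_TO_SERIES_REGION <- c(head = "head", neck = "neck", chest = "chest",
                            abdomen = "abdomen_pelvis",
                            pelvis = "abdomen_pelvis")

## Deterministic per-study stream: cohorts are extensible without
## re-drawing earlier studies. Kept strictly below 2^31 - 1.
study_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

generate_study <- function(i, config) {
  set.seed(study_seed(config$seed, i))
  scanner <- sample(names(config$scanner_mix), 1L, prob = config$scanner_mix)
  alias1 <- sample(names(config$study_alias_mix), 1L,
                   prob = config$study_alias_mix)
  multi <- stats::runif(1) < config$multi_region_prob
  aliases <- alias1
  if (multi) {
    ## second region must differ at series level, so e.g. abdomen+pelvis
    ## (both mapping to abdomen_pelvis) never collapses the draw
    others <- names(config$study_alias_mix)[
      ALIAS_TO_SERIES_REGION[names(config$study_alias_mix)] !=
        ALIAS_TO_SERIES_REGION[[alias1]]]
    aliases <- c(alias1, sample(others, 1L,
                                prob = config$study_alias_mix[others]))
  }
  regions <- unique(unname(ALIAS_TO_SERIES_REGION[aliases]))
  am <- config$age_model; wm <- config$weight_model; dm <- config$deff_model
  age <- rtruncnorm(1, am$mean, am$sd, am$lo, am$hi)
  weight <- rtruncnorm(1, wm$mean, wm$sd, wm$lo, wm$hi)
  sex <- sample(c("F", "M", "unknown"), 1L, prob = c(0.519, 0.480, 0.001))
  study_id <- sprintf("S%06d", i)

  proto_word <- c(head = "HEAD ROUTINE", neck = "NECK SOFT TISSUE",
                  chest = "CHEST HRCT", abdomen_pelvis = "ABDOMEN+PELVIS PORTAL",
                  trunk = "TRUNK POLYTRAUMA")
  rows <- list()
  k <- 0L
  for (reg in regions) {
    win <- config$scan_length_windows[[reg]]
    phantom <- if (reg == "head") "head16" else "body32"
    d_eff <- if (reg == "head") {
      stats::rnorm(1, dm$head_mean, dm$head_sd)
    } else {
      dm$slope * weight + dm$intercept + stats::rnorm(1, 0, dm$sd)
    }
    d_eff <- min(max(d_eff, 8), 55)
    for (acq in c("scout", "helical")) {
      k <- k + 1L
      median_ctdi <- if (acq == "scout") config$ctdi_model$scout_median
                     else config$ctdi_model[[reg]]
      ctdi <- stats::rlnorm(1, log(median_ctdi), config$ctdi_model$sdlog)
      len <- stats::runif(1, win[1L], win[2L])
      rows[[k]] <- data.frame(
        study_id = study_id,
        series_uid = sprintf("1.2.826.%d.%d", i, k),
        scanner_id = scanner,
        protocol_name = proto_word[[reg]],
        series_region = reg,
        acquisition_type = acq,
        ctdi_vol = ctdi,
        phantom = phantom,
        dlp = ctdi * len,
        scan_length = len,
        d_eff = if (acq == "helical") d_eff else NA_real_,
        d_water = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(study = data.frame(study_id = study_id, patient_age = age,
                          patient_sex = sex, patient_weight = weight,
                          study_alias = alias1, stringsAsFactors = FALSE),
       series = do.call(rbind, rows),
       truth = data.frame(study_id = study_id, multi_region = multi,
                          weight = weight,
                          regions = paste(regions, collapse = "+"),
                          stringsAsFactors = FALSE))
}

#' Generate a seeded synthetic two-view cohort
#'
#' Produces a region-correct monitoring-system view (`dms_view`), a
#' commercial view (`dw_view`) sharing every study and series UID but with
#' fixed-region misassignment applied when enabled, and a truth ledger
#' recording the latent draws (true regions, weights, multi-region flags).
#' Each study has its own RNG stream keyed by `(seed, study index)`, so the
#' same seed always reproduces the same cohort byte for byte and enlarging
#' `n_studies` never re-draws earlier studies. Every generated series
#' satisfies DLP = CTDIvol × scan length exactly.
#'
#' @param config a [cohort_config()]
#' @return list with `dms_view`, `dw_view` (both [ct_cohort]s) and `truth`
#'   (list of `studies` data.frame and the echoed config)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    ctda_error("ctda_config_error", "config must be a cohort_config()")
  }
  with_preserved_rng({
    parts <- lapply(seq_len(config$n_studies), generate_study, config = config)
    studies <- do.call(rbind, lapply(parts, `[[`, "study"))
    series <- do.call(rbind, lapply(parts, `[[`, "series"))
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    rownames(studies) <- rownames(series) <- rownames(truth) <- NULL
    dms <- ct_cohort(studies, series)
    dw <- if (config$misassignment) emulate_fixed_region(dms) else dms
    list(dms_view = dms, dw_view = dw,
         truth = list(studies = truth, config = config))
  })
}

#' Generate a cohort with injected linear SED structure
#'
#' Parameter-recovery harness: SSDE is computed from the generated geometry
#' (CTDIvol, effective diameter, phantom), and per-series SED values are
#' drawn as `a·SSDE − b + Normal(0, noise_sd)` with region-specific `(a, b)`.
#' Downstream OLS fits should recover the injected coefficients within
#' sampling error, which makes the whole fit/compare path testable against
#' generator ground truth.
#'
#' @param config a [cohort_config()]
#' @param region_slopes named list, one entry per series region present,
#'   each `c(a = , b = )`
#' @param noise_sd standard deviation of the additive noise, mSv (>= 0)
#' @return list with `cohort` (the region-correct view), `points`
#'   (data.frame `region`, `scanner_id`, `ssde`, `sed`), and `truth`
#' @export
inject_linear_sed_structure <- function(config, region_slopes, noise_sd = 0) {
  if (noise_sd < 0) ctda_error("ctda_config_error", "noise_sd must be >= 0")
  gen <- generate_cohort(config)
  series <- gen$dms_view$series
  diag <- series[series$acquisition_type != "scout" & !is.na(series$d_eff), ]
  unknown <- setdiff(unique(diag$series_region), names(region_slopes))
  if (length(unknown)) {
    ctda_error("ctda_config_error", "no injected slope for region '%s'",
               unknown[1L])
  }
  ssde <- mapply(function(ctdi, d, ph) ssde_from_deff(ctdi, d, ph),
                 diag$ctdi_vol, diag$d_eff, diag$phantom)
  ab <- do.call(rbind, region_slopes[diag$series_region])
  with_preserved_rng({
    set.seed(study_seed(config$seed, 999983L))
    sed <- ab[, "a"] * ssde - ab[, "b"] + stats::rnorm(length(ssde), 0, noise_sd)
  })
  list(cohort = gen$dms_view,
       points = data.frame(region = diag$series_region,
                           scanner_id = diag$scanner_id,
                           ssde = ssde, sed = unname(sed),
                           stringsAsFactors = FALSE),
       truth = gen$truth)
}
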