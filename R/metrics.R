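#' Quadratic weight-correction model
#'
#' The dimensionless factor wkg = c0 + c1·w + c2·w² rescales effective dose
#' for patient weight w (kg); it equals ~1 near 70 kg (the reference adult)
#' and decreases with weight up to the parabola vertex at −c1/(2·c2) ≈ 165 kg.
#' Defaults: c0 = 1.73, c1 = −1.33e−2 per kg, c2 = 4.04e−5 per kg².
#'
#' @param c0,c1,c2 polynomial coefficients
#' @param valid_weight_range kg interval outside which [compute_wkg()] errors
#' @return a `weight_correction` object
#' @export
weight_correction <- function(c0 = 1.73, c1 = -1.33e-2, c2 = 4.04e-5,
                              valid_weight_range = c(20, 200)) {
  structure(list(c0 = c0, c1 = c1, c2 = c2,
                 valid_weight_range = valid_weight_range),
            class = "weight_correction")
}

#' Weight-correction factor wkg
#'
#' @param w patient weight in kg (vectorised)
#' @param model a [weight_correction()] model
#' @param check_range if `TRUE` (default), weights outside the model's valid
#'   range raise a range error naming the offending weight
#' @return dimensionless factor(s)
#' @export
compute_wkg <- function(w, model = weight_correction(), check_range = TRUE) {
  if (check_range) {
    bad <- which(!is.na(w) & (w < model$valid_weight_range[1L] |
                              w > model$valid_weight_range[2L]))
    if (length(bad)) {
      ctda_error("ctda_range_error", "weight %g kg outside valid range [%g, %g]",
                 w[bad[1L]], model$valid_weight_range[1L], model$valid_weight_range[2L])
    }
  }
  model$c0 + model$c1 * w + model$c2 * w^2
}

lookup_factor <- function(region, table) {
  f <- unclass(table)[region]
  bad <- which(is.na(f))
  if (length(bad)) {
    ctda_error("ctda_lookup_error", "no conversion factor for region '%s'",
               region[bad[1L]])
  }
  unname(f)
}

#' Effective dose from DLP
#'
#' ED (mSv) = DLP (mGy·cm) × f (mSv/mGy·cm) with the region's conversion
#' factor. Vectorised over `dlp`/`region`.
#'
#' @param dlp dose-length product, mGy·cm, non-negative
#' @param region series region label(s) with an entry in `table`
#' @param table a [conversion_factors()] table
#' @return effective dose in mSv
#' @export
compute_ed <- function(dlp, region, table = conversion_factors()) {
  if (any(dlp < 0, na.rm = TRUE)) ctda_error("ctda_range_error", "negative dlp")
  lookup_factor(region, table) * dlp
}

#' Weight-corrected (size-specific) effective dose from DLP
#'
#' SED = wkg(w) × f × DLP; exactly equal to `compute_wkg(w) * compute_ed(...)`.
#' A missing weight is a distinct error from an out-of-range weight, because
#' the quantity is undefined without it — no silent default is applied.
#'
#' @inheritParams compute_ed
#' @param w patient weight, kg
#' @param wmodel a [weight_correction()] model
#' @return SED in mSv
#' @export
compute_sed <- function(dlp, region, table = conversion_factors(), w,
                        wmodel = weight_correction()) {
  if (missing(w) || anyNA(w)) {
    ctda_error("ctda_missing_weight", "patient weight required for SED")
  }
  compute_wkg(w, wmodel) * compute_ed(dlp, region, table)
}

#' Size-specific dose estimate from effective diameter
#'
#' SSDE (mGy) = CTDIvol · a_e · exp(−b_e · D_eff), with phantom-specific
#' exponential coefficients. Diameters outside (6, 60) cm are rejected to
#' guard against mm/cm unit mix-ups.
#'
#' @param ctdi_vol volume CT dose index, mGy, non-negative (vectorised)
#' @param d_eff patient effective diameter, cm, in (6, 60)
#' @param phantom `"body32"` or `"head16"`
#' @param model an [ssde_model()]
#' @return SSDE in mGy
#' @export
ssde_from_deff <- function(ctdi_vol, d_eff, phantom = c("body32", "head16"),
                           model = ssde_model()) {
  phantom <- match.arg(phantom)
  bad <- which(!is.na(d_eff) & (d_eff <= 6 | d_eff >= 60))
  if (length(bad)) {
    ctda_error("ctda_range_error",
               "d_eff %g cm outside plausible range (6, 60) — check units", d_eff[bad[1L]])
  }
  if (any(ctdi_vol < 0, na.rm = TRUE)) ctda_error("ctda_range_error", "negative ctdi_vol")
  co <- model[[phantom]]
  ctdi_vol * co[["a_e"]] * exp(-co[["b_e"]] * d_eff)
}

#' Map effective-diameter SSDE onto the water-equivalent-diameter basis
#'
#' Applies a configured linear relationship `slope · SSDE(Deff) + intercept`
#' for the thoracic regions it was calibrated on. Requires an explicit
#' [dwater_map()]; there is no default and no silent identity.
#'
#' @param ssde_deff SSDE computed from the effective diameter, mGy
#' @param map a configured [dwater_map()]
#' @param region region the value belongs to; must be in `map$regions`
#' @return SSDE on the Dwater basis, mGy
#' @export
ssde_to_dwater_basis <- function(ssde_deff, map, region) {
  if (missing(map) || is.null(map) || !inherits(map, "dwater_map")) {
    ctda_error("ctda_config_error", "dwater_map coefficients required")
  }
  bad <- setdiff(unique(region), map$regions)
  if (length(bad)) {
    ctda_error("ctda_lookup_error",
               "dwater map not applicable to region '%s'", bad[1L])
  }
  map$slope * ssde_deff + map$intercept
}

#' SED estimated from SSDE via published regression segments
#'
#' Looks up the unique segment matching the scanned region and scan length
#' and evaluates its linear map (default convention a·SSDE − b). Scan lengths
#' outside every calibrated window raise an out-of-calibrated-range error; a
#' negative result is returned as-is with a warning and a `negative`
#' attribute (clamping would bias downstream slope comparisons).
#'
#' @param ssde SSDE in mGy (vectorised; one region/length per call)
#' @param scanned_region one of the segment regions (`chest`,
#'   `abdomen_pelvis`, `cap`, `abdomen`, `chest_abdomen`)
#' @param scan_length cm
#' @param segments segment table, see [martin_segments()]
#' @return SED in mSv, possibly with attribute `negative` (logical vector)
#' @export
sed_from_ssde <- function(ssde, scanned_region, scan_length,
                          segments = martin_segments()) {
  hit <- segments$region == scanned_region &
    segments$length_lo <= scan_length & scan_length <= segments$length_hi
  if (sum(hit) == 0L) {
    ctda_error("ctda_range_error",
               "scan length %g cm out of calibrated range for region '%s'",
               scan_length, scanned_region)
  }
  if (sum(hit) > 1L) {
    ctda_error("ctda_config_error",
               "multiple segments match region '%s' at %g cm", scanned_region,
               scan_length)
  }
  seg <- segments[hit, ]
  out <- if (identical(seg$sign_convention, "a_x_plus_b")) {
    seg$a * ssde + seg$b
  } else {
    seg$a * ssde - seg$b
  }
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sprintf("negative SED from linear map for region '%s' (min %.3g mSv)",
                    scanned_region, min(out[neg])), call. = FALSE)
    attr(out, "negative") <- neg
  }
  out
}

#' Total study effective dose
#'
#' Sums per-series ED (or weight-corrected SED) over each study, each series
#' converted with its *own* region's factor. Under fixed-region
#' misassignment, low-factor series inherit a high factor and the total is
#' inflated — the mechanism this audit quantifies.
#'
#' @param cohort a [ct_cohort]
#' @param table a [conversion_factors()] table
#' @param weight_corrected if `TRUE`, multiply each study total by its
#'   patient's wkg factor (weight required)
#' @param wmodel a [weight_correction()] model
#' @return named numeric vector of mSv totals, one per study
#' @export
study_ed_total <- function(cohort, table = conversion_factors(),
                           weight_corrected = FALSE,
                           wmodel = weight_correction()) {
  series <- cohort$series
  known <- series$series_region %in% names(unclass(table))
  if (any(!known)) {
    off <- series[!known, ][1L, ]
    ctda_error("ctda_lookup_error",
               "no conversion factor for region '%s' (series %s)",
               off$series_region, off$series_uid)
  }
  ed <- compute_ed(series$dlp, series$series_region, table)
  totals <- tapply(ed, factor(series$study_id, levels = cohort$studies$study_id),
                   sum)
  totals <- stats::setNames(as.numeric(totals), cohort$studies$study_id)
  if (weight_corrected) {
    w <- cohort$studies$patient_weight
    if (anyNA(w)) {
      ctda_error("ctda_missing_weight",
                 "patient weight required for SED (study %s)",
                 cohort$studies$study_id[which(is.na(w))[1L]])
    }
    totals <- totals * compute_wkg(w, wmodel)
  }
  totals
}
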