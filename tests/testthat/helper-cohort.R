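# Fixture builders: tiny cohorts constructed in code, no files on disk.

mk_series <- function(study_id, series_uid, region, acq = "helical",
                      ctdi = 10, len = 40, dlp = ctdi * len, d_eff = 30,
                      scanner = "CT1", phantom = "body32",
                      protocol = "TEST PROTO") {
  data.frame(study_id = study_id, series_uid = series_uid,
             scanner_id = scanner, protocol_name = protocol,
             series_region = region, acquisition_type = acq,
             ctdi_vol = ctdi, phantom = phantom, dlp = dlp,
             scan_length = len, d_eff = d_eff, d_water = NA_real_,
             stringsAsFactors = FALSE)
}

mk_study <- function(study_id, age = 60, sex = "F", weight = 70,
                     alias = "chest") {
  data.frame(study_id = study_id, patient_age = age, patient_sex = sex,
             patient_weight = weight, study_alias = alias,
             stringsAsFactors = FALSE)
}

# A two-series head+chest study, chest last: the canonical misassignment case.
mk_head_chest_cohort <- function(id = "S1") {
  ct_cohort(
    mk_study(id, alias = "head"),
    rbind(mk_series(id, paste0(id, ".1"), "head", ctdi = 60, len = 15,
                    dlp = 900, d_eff = 17, phantom = "head16"),
          mk_series(id, paste0(id, ".2"), "chest", ctdi = 10, len = 35,
                    dlp = 350, d_eff = 28)))
}

# Independent OLS oracle: explicit normal equations, no lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Independent quartile oracle: sort and linearly interpolate at p(n-1)+1.
quartile_oracle <- function(values, p) {
  v <- sort(values)
  h <- p * (length(v) - 1) + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
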