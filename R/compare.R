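## Rounding used for all printed integer percentages: half away from zero
## (so 11.52 -> 12, 2.557 -> 3), not R's banker's rounding.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Ordinary least-squares line fit
#'
#' Plain OLS with intercept, y = a·x + b, as used for every region/scanner
#' metric pair in the audit. No weighting, no robust loss.
#'
#' @param x,y numeric vectors of equal length >= 2; `x` must not be constant
#' @param x_metric,y_metric,region,scanner_id optional labels carried on the
#'   result
#' @return a `ctda_fit` list: `slope`, `intercept`, `r2`, `n`, plus labels
#' @export
fit_linear <- function(x, y, x_metric = "x", y_metric = "y",
                       region = NA_character_, scanner_id = NA_character_) {
  if (length(x) != length(y)) {
    ctda_error("ctda_validation_error", "x and y lengths differ (%d vs %d)",
               length(x), length(y))
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) {
    ctda_error("ctda_validation_error", "need >= 2 complete observations")
  }
  if (stats::var(x) == 0) {
    ctda_error("ctda_degenerate_design", "constant x: slope is not identifiable")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 r2 = r2, n = length(x),
                 x_metric = x_metric, y_metric = y_metric,
                 region = region, scanner_id = scanner_id),
            class = "ctda_fit")
}

#' @export
print.ctda_fit <- function(x, ...) {
  cat(sprintf("<fit %s ~ %s%s> y = %.4gx %+.4g, R2 = %.3f, n = %d\n",
              x$y_metric, x$x_metric,
              if (is.na(x$region)) "" else sprintf(" [%s/%s]", x$region, x$scanner_id),
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Absolute percent difference between two slopes
#'
#' `| |observed| − |reference| | / |reference| × 100`, rounded half away from
#' zero to an integer (the convention used for printed slope tables).
#' Comparison is on magnitudes, so the result is invariant to simultaneous
#' or individual sign flips — a negative published reference slope compares
#' like its magnitude.
#'
#' @param observed,reference slopes; `reference` must be nonzero
#' @param rounded if `FALSE`, return the unrounded percent difference
#' @return percent difference (integer unless `rounded = FALSE`)
#' @export
slope_pct_diff <- function(observed, reference, rounded = TRUE) {
  if (any(reference == 0)) {
    ctda_error("ctda_validation_error", "zero reference slope")
  }
  pct <- abs(abs(observed) - abs(reference)) / abs(reference) * 100
  if (rounded) as.integer(round_half_away(pct)) else pct
}

#' Mean and range of absolute percent differences
#'
#' Arithmetic mean of a set of (unrounded) percent differences, reported to
#' one decimal, together with the min/max range.
#'
#' @param diffs non-empty numeric vector of percent differences
#' @return list `mean` (1 decimal), `min`, `max`, `mean_unrounded`
#' @export
mean_abs_pct_diff <- function(diffs) {
  if (length(diffs) == 0L) {
    ctda_error("ctda_validation_error", "empty percent-difference list")
  }
  m <- mean(diffs)
  list(mean = round(m, 1), min = min(diffs), max = max(diffs),
       mean_unrounded = m)
}

#' Region/scanner-stratified slope comparison table
#'
#' For each reference segment region and each scanner, fits SED ~ SSDE and
#' ED ~ SSDE by OLS and compares both observed slopes to the published
#' reference slope as absolute percent differences. Cells with fewer than
#' two points are emitted empty (`NA`), mirroring cohorts where a scanner
#' never ran a given exam type. Rows whose region has no reference segment
#' are flagged and excluded from the summary means, which are computed from
#' the unrounded differences and reported to one decimal.
#'
#' @param points data.frame with columns `region` (segment vocabulary),
#'   `scanner_id`, `ssde`, `sed`, `ed`
#' @param segments reference segment table, see [martin_segments()]
#' @param scanners scanners to tabulate (default: those present)
#' @return a `ctda_slope_table` list: `table` (one row per region × scanner),
#'   `sed_summary`, `ed_summary` (each a [mean_abs_pct_diff()] result)
#' @export
build_slope_table <- function(points, segments = martin_segments(),
                              scanners = NULL) {
  if (is.null(scanners)) scanners <- sort(unique(points$scanner_id))
  regions <- unique(c(segments$region, setdiff(unique(points$region),
                                               segments$region)))
  rows <- list()
  for (reg in regions) {
    ref <- segments$a[segments$region == reg]
    has_ref <- length(ref) == 1L
    for (sc in scanners) {
      sub <- points[points$region == reg & points$scanner_id == sc, , drop = FALSE]
      row <- data.frame(region = reg, scanner_id = sc, n = nrow(sub),
                        sed_slope = NA_real_, sed_intercept = NA_real_,
                        sed_r2 = NA_real_, ed_slope = NA_real_,
                        ed_intercept = NA_real_, ed_r2 = NA_real_,
                        reference_slope = if (has_ref) ref else NA_real_,
                        sed_pct_diff = NA_real_, ed_pct_diff = NA_real_,
                        sed_pct_diff_unrounded = NA_real_,
                        ed_pct_diff_unrounded = NA_real_,
                        no_reference = !has_ref,
                        stringsAsFactors = FALSE)
      if (nrow(sub) >= 2L && stats::var(sub$ssde) > 0) {
        fs <- fit_linear(sub$ssde, sub$sed, "ssde", "sed", reg, sc)
        fe <- fit_linear(sub$ssde, sub$ed, "ssde", "ed", reg, sc)
        row$sed_slope <- fs$slope; row$sed_intercept <- fs$intercept
        row$sed_r2 <- fs$r2
        row$ed_slope <- fe$slope; row$ed_intercept <- fe$intercept
        row$ed_r2 <- fe$r2
        if (has_ref) {
          row$sed_pct_diff <- slope_pct_diff(fs$slope, ref)
          row$ed_pct_diff <- slope_pct_diff(fe$slope, ref)
          row$sed_pct_diff_unrounded <- slope_pct_diff(fs$slope, ref, rounded = FALSE)
          row$ed_pct_diff_unrounded <- slope_pct_diff(fe$slope, ref, rounded = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  usable <- !tab$no_reference
  sed_d <- tab$sed_pct_diff_unrounded[usable]
  ed_d <- tab$ed_pct_diff_unrounded[usable]
  sed_summary <- if (any(!is.na(sed_d))) mean_abs_pct_diff(sed_d[!is.na(sed_d)]) else NULL
  ed_summary <- if (any(!is.na(ed_d))) mean_abs_pct_diff(ed_d[!is.na(ed_d)]) else NULL
  structure(list(table = tab, sed_summary = sed_summary, ed_summary = ed_summary),
            class = "ctda_slope_table")
}

#' @export
print.ctda_slope_table <- function(x, ...) {
  cat("<slope comparison table>\n")
  print(x$table[c("region", "scanner_id", "n", "sed_slope", "ed_slope",
                  "reference_slope", "sed_pct_diff", "ed_pct_diff")])
  if (!is.null(x$sed_summary)) {
    cat(sprintf("mean |pct diff| SED: %.1f (%.3g-%.3g)\n",
                x$sed_summary$mean, x$sed_summary$min, x$sed_summary$max))
  }
  if (!is.null(x$ed_summary)) {
    cat(sprintf("mean |pct diff| ED:  %.1f (%.3g-%.3g)\n",
                x$ed_summary$mean, x$ed_summary$min, x$ed_summary$max))
  }
  invisible(x)
}

#' Serialise a slope table
#' @param x a `ctda_slope_table`
#' @param path output path (`.csv` or `.json` decided by `format`)
#' @param format `"csv"` or `"json"`
#' @export
write_slope_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(x$table, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(list(table = x$table, sed_summary = x$sed_summary,
                              ed_summary = x$ed_summary),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(path)
}

#' Box-plot summary statistics
#'
#' Median and quartiles by linear interpolation (type-7 quantiles), with
#' whiskers at the most extreme data points within 1.5·IQR of the box edges
#' — the usual box-and-whisker convention.
#'
#' @param values non-empty numeric vector (`NA`s dropped)
#' @return a `ctda_box` list: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`
#' @export
summarize_box <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    ctda_error("ctda_validation_error", "no values to summarise")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  structure(list(n = length(values), median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_lo = min(values[values >= lo_fence]),
                 whisker_hi = max(values[values <= hi_fence])),
            class = "ctda_box")
}

#' @export
print.ctda_box <- function(x, ...) {
  cat(sprintf("<box n=%d> %.3g [%.3g | %.3g | %.3g] %.3g\n", x$n,
              x$whisker_lo, x$q1, x$median, x$q3, x$whisker_hi))
  invisible(x)
}
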