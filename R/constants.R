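#' DLP-to-ED conversion factor tables
#'
#' Region-specific conversion factors f (mSv per mGy·cm) turning dose-length
#' product into effective dose, ED = f × DLP. Two default tables ship with
#' the package: `"aapm_rpt96"`-style adult factors (head 0.0021, neck 0.0059,
#' chest 0.014, abdomen/pelvis 0.015) and `"deak2010"`-style adult factors at
#' 120 kVp. Neither cited publication defines a factor for a trunk
#' (chest+abdomen+pelvis) acquisition; the default is the mean of the three
#' component factors and can be overridden. Supplying `factors` with
#' `source = "custom"` replaces the table entirely.
#'
#' @param source `"aapm_rpt96"`, `"deak2010"`, or `"custom"`
#' @param factors named numeric vector over series regions (required for
#'   `"custom"`, optional overrides otherwise)
#' @return a `conversion_factors` object (named numeric with a `source`
#'   attribute)
#' @export
conversion_factors <- function(source = c("aapm_rpt96", "deak2010", "custom"),
                               factors = NULL) {
  source <- match.arg(source)
  defaults <- switch(source,
    aapm_rpt96 = c(head = 0.0021, neck = 0.0059, chest = 0.014,
                   abdomen_pelvis = 0.015,
                   trunk = mean(c(0.014, 0.015, 0.015))),
    deak2010 = c(head = 0.0019, neck = 0.0051, chest = 0.0145,
                 abdomen_pelvis = 0.0153,
                 trunk = mean(c(0.0145, 0.0153, 0.0129))),
    custom = NULL)
  f <- defaults
  if (!is.null(factors)) {
    if (is.null(f)) f <- factors else f[names(factors)] <- factors
  }
  needed <- setdiff(SERIES_REGIONS, "undefined")
  missing <- setdiff(needed, names(f))
  if (length(missing)) {
    ctda_error("ctda_config_error", "conversion factors missing region(s): %s",
               paste(missing, collapse = ", "))
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    ctda_error("ctda_config_error", "conversion factors must be finite and > 0")
  }
  structure(f[needed], source = source, class = "conversion_factors")
}

#' @export
print.conversion_factors <- function(x, ...) {
  cat(sprintf("<conversion_factors source=%s> mSv/(mGy*cm)\n", attr(x, "source")))
  print(unclass(x))
  invisible(x)
}

#' SSDE conversion model
#'
#' Exponential size-conversion coefficients turning CTDIvol into a
#' size-specific dose estimate: SSDE = CTDIvol · a_e · exp(−b_e · D), with D
#' the patient diameter in cm. Defaults follow the published AAPM fits for
#' the 32 cm body phantom (a_e = 3.704369, b_e = 0.03671937) and the 16 cm
#' head phantom (a_e = 1.9852, b_e = 0.0486). The conversion factor is
#' strictly decreasing in D and equals exactly 1 at D = ln(a_e)/b_e.
#'
#' @param body32,head16 numeric vectors `c(a_e = , b_e = )`, both positive
#' @return an `ssde_model` object
#' @export
ssde_model <- function(body32 = c(a_e = 3.704369, b_e = 0.03671937),
                       head16 = c(a_e = 1.9852, b_e = 0.0486)) {
  m <- list(body32 = body32, head16 = head16)
  for (ph in names(m)) {
    co <- m[[ph]]
    if (!all(c("a_e", "b_e") %in% names(co)) || any(co <= 0)) {
      ctda_error("ctda_config_error", "ssde_model %s needs positive a_e, b_e", ph)
    }
  }
  structure(m, class = "ssde_model")
}

#' Linear map from effective-diameter SSDE to water-equivalent-diameter SSDE
#'
#' SSDE computed from the geometric effective diameter can be mapped onto the
#' water-equivalent-diameter basis for thoracic acquisitions via a published
#' linear relationship. No default coefficients ship with the package — the
#' map must be configured explicitly; using it unconfigured is an error,
#' never a silent identity.
#'
#' @param slope,intercept linear coefficients (slope > 0)
#' @param regions regions the map applies to
#' @return a `dwater_map` object
#' @export
dwater_map <- function(slope, intercept = 0,
                       regions = c("chest", "chest_abdomen")) {
  if (missing(slope) || !is.finite(slope) || slope <= 0) {
    ctda_error("ctda_config_error", "dwater_map coefficients required (slope > 0)")
  }
  structure(list(slope = slope, intercept = intercept, regions = regions),
            class = "dwater_map")
}

#' Published SED–SSDE regression segments
#'
#' Region- and scan-length-specific linear segments SED = a·SSDE − b (mSv)
#' from Monte Carlo phantom dosimetry, each valid only within its calibrated
#' scan-length window (cm): abdomen-pelvis 40–50, chest 30–37,
#' chest-abdomen-pelvis (cap) 62–70, abdomen 15–30, chest-abdomen 40–50.
#' The abdomen slope is stored as its magnitude 0.3793 with
#' `printed_sign = -1`: the source table prints it negative while the
#' percent differences reported against it imply comparison on magnitudes.
#' That discrepancy is carried explicitly rather than resolved silently;
#' slope comparisons in this package are sign-flip invariant.
#'
#' @return data.frame with columns `region`, `length_lo`, `length_hi`, `a`,
#'   `b`, `sign_convention`, `printed_sign`
#' @export
martin_segments <- function() {
  data.frame(
    region = c("chest", "abdomen_pelvis", "cap", "abdomen", "chest_abdomen"),
    length_lo = c(30, 40, 62, 15, 40),
    length_hi = c(37, 50, 70, 30, 50),
    a = c(0.5708, 0.6813, 1.0599, 0.3793, 0.7798),
    b = c(1.2599, 2.3621, 2.9980, 1.7078, 0.8491),
    sign_convention = "a_x_minus_b",
    printed_sign = c(1, 1, 1, -1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read / write a constant table as JSON
#'
#' Conversion factors, SSDE coefficients and regression segments are plain
#' data; these helpers serialise them with a provenance string so sites can
#' version their own tables.
#' @param x object to serialise
#' @param path file path
#' @param source provenance string stored alongside the values
#' @rdname constant_table_io
#' @export
write_constant_table <- function(x, path, source = attr(x, "source")) {
  payload <- list(source = if (is.null(source)) "unspecified" else source,
                  values = if (is.data.frame(x)) x else as.list(unclass(x)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname constant_table_io
#' @export
read_constant_table <- function(path) {
  payload <- jsonlite::fromJSON(path)
  x <- payload$values
  if (!is.data.frame(x)) x <- unlist(x)
  attr(x, "source") <- payload$source
  x
}
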