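test_that("wkg polynomial evaluates and guards its range", {
  expect_equal(compute_wkg(70), 0.99696)
  expect_equal(compute_wkg(100), 0.804)
  expect_equal(compute_wkg(0, check_range = FALSE), 1.73)
  expect_error(compute_wkg(10), "10", class = "ctda_range_error")
  expect_error(compute_wkg(250), class = "ctda_range_error")
})

test_that("wkg is strictly decreasing up to its vertex and crosses 1 near 69.6 kg", {
  w <- seq(20, 164.6, by = 0.1)
  v <- compute_wkg(w)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0))
  # brute-force bisection oracle for the unit crossing
  f <- function(w) compute_wkg(w) - 1
  lo <- 20; hi <- 164
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 69.6, tolerance = 0.005)
})

test_that("compute_ed multiplies DLP by the region factor", {
  tab <- conversion_factors("custom",
                            c(head = 0.0021, neck = 0.0059, chest = 0.014,
                              abdomen_pelvis = 0.015, trunk = 0.0147))
  expect_equal(compute_ed(100, "chest", tab), 1.4)
  expect_equal(compute_ed(0, "chest", tab), 0)
  expect_equal(compute_ed(1000, "head", tab), 2.1)
  expect_error(compute_ed(100, "undefined", tab), class = "ctda_lookup_error")
  expect_error(compute_ed(-1, "chest", tab), class = "ctda_range_error")
  # linearity against brute-force recomputation on random inputs
  set.seed(5)
  dlp <- runif(200, 0, 2000)
  reg <- sample(names(unclass(tab)), 200, TRUE)
  expect_equal(compute_ed(dlp, reg, tab),
               vapply(seq_along(dlp),
                      function(i) unclass(tab)[[reg[i]]] * dlp[i], numeric(1)),
               tolerance = 1e-12)
})

test_that("SED = wkg * ED exactly, with distinct missing-weight error", {
  tab <- conversion_factors("custom",
                            c(head = 0.0021, neck = 0.0059, chest = 0.014,
                              abdomen_pelvis = 0.015, trunk = 0.0147))
  expect_equal(compute_sed(100, "chest", tab, w = 70), 1.4 * 0.99696)
  expect_equal(compute_sed(100, "chest", tab, w = 100), 1.1256)
  set.seed(9)
  dlp <- runif(100, 0, 1500); w <- runif(100, 40, 150)
  reg <- sample(c("head", "chest", "abdomen_pelvis"), 100, TRUE)
  expect_equal(compute_sed(dlp, reg, tab, w = w),
               compute_wkg(w) * compute_ed(dlp, reg, tab))
  expect_error(compute_sed(100, "chest", tab, w = NA_real_),
               class = "ctda_missing_weight")
  err_range <- tryCatch(compute_sed(100, "chest", tab, w = 5), error = identity)
  expect_s3_class(err_range, "ctda_range_error")
  expect_false(inherits(err_range, "ctda_missing_weight"))
})

test_that("SSDE is CTDIvol times a decreasing exponential of diameter", {
  m <- ssde_model()
  unity <- log(m$body32[["a_e"]]) / m$body32[["b_e"]]
  expect_equal(ssde_from_deff(10, unity, "body32", m), 10)
  expect_equal(ssde_from_deff(10, 30, "body32", m), 12.31, tolerance = 5e-4)
  expect_equal(ssde_from_deff(0, 30), 0)
  d <- seq(8, 55, by = 0.5)
  factor <- ssde_from_deff(1, d)
  expect_true(all(diff(factor) < 0) && all(factor > 0))
  # unit-mix-up guard: 300 mm is not 30 cm
  expect_error(ssde_from_deff(10, 300), "units", class = "ctda_range_error")
  expect_error(ssde_from_deff(-1, 30), class = "ctda_range_error")
})

test_that("Dwater-basis mapping requires explicit coefficients and region", {
  expect_equal(ssde_to_dwater_basis(8.5, dwater_map(1, 0), "chest"), 8.5)
  expect_equal(ssde_to_dwater_basis(10, dwater_map(1.1, -0.5), "chest"), 10.5)
  expect_error(ssde_to_dwater_basis(10, dwater_map(1.1, -0.5), "head"),
               class = "ctda_lookup_error")
  expect_error(ssde_to_dwater_basis(10, NULL, "chest"),
               "coefficients required", class = "ctda_config_error")
})

test_that("sed_from_ssde applies the matching calibrated segment", {
  seg <- martin_segments()
  expect_equal(sed_from_ssde(10, "abdomen_pelvis", 45, seg), 4.4509)
  # root of the linear map
  ab <- seg[seg$region == "chest", ]
  expect_equal(sed_from_ssde(ab$b / ab$a, "chest", 33, seg), 0)
  expect_error(sed_from_ssde(10, "abdomen_pelvis", 60, seg),
               "out of calibrated range", class = "ctda_range_error")
  # negative results warn and are flagged, never clamped
  expect_warning(v <- sed_from_ssde(0.5, "abdomen_pelvis", 45, seg),
                 "negative SED")
  expect_lt(as.numeric(v), 0)
  expect_true(attr(v, "negative"))
  # affine in the dose argument (brute force on random ssde)
  set.seed(3)
  s <- runif(50, 2, 30)
  expect_equal(as.numeric(suppressWarnings(sed_from_ssde(s, "cap", 65, seg))),
               1.0599 * s - 2.9980, tolerance = 1e-12)
})

test_that("study ED totals use each series' own region", {
  tab <- conversion_factors("custom",
                            c(head = 0.0021, neck = 0.0059, chest = 0.014,
                              abdomen_pelvis = 0.015, trunk = 0.0147))
  cohort <- mk_head_chest_cohort()
  expect_equal(unname(study_ed_total(cohort, tab)), 6.79)
  fixed <- emulate_fixed_region(cohort)
  expect_equal(unname(study_ed_total(fixed, tab)), 17.5)
  # singleton study equals compute_ed of its one series
  one <- ct_cohort(mk_study("B"), mk_series("B", "b1", "chest", dlp = 123))
  expect_equal(unname(study_ed_total(one, tab)),
               compute_ed(123, "chest", tab))
  # lookup failures name the offending series
  und <- ct_cohort(mk_study("C"), mk_series("C", "c77", "undefined"))
  expect_error(study_ed_total(und, tab), "c77", class = "ctda_lookup_error")
  # weight-corrected totals need a weight
  noweight <- ct_cohort(mk_study("D", weight = NA_real_),
                        mk_series("D", "d1", "chest"))
  expect_error(study_ed_total(noweight, tab, weight_corrected = TRUE),
               class = "ctda_missing_weight")
})

test_that("fixed-region misassignment inflates ED when the high-factor region is last", {
  tab <- conversion_factors("aapm_rpt96")
  gen <- generate_cohort(cohort_config(n_studies = 120, seed = 23,
                                       multi_region_prob = 0.35))
  correct <- study_ed_total(gen$dms_view, tab)
  fixed <- study_ed_total(gen$dw_view, tab)
  multi <- gen$truth$studies$multi_region
  # single-region studies are untouched
  expect_equal(fixed[!multi], correct[!multi])
  # and for the canonical head-then-chest study the inflation is strict
  hc <- mk_head_chest_cohort()
  expect_gt(unname(study_ed_total(emulate_fixed_region(hc), tab)),
            unname(study_ed_total(hc, tab)))
})
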