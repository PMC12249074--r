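test_that("fit_linear is plain OLS with intercept", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  f2 <- fit_linear(c(0, 1), c(0, 3))
  expect_equal(f2$slope, 3)
  expect_equal(f2$intercept, 0)
  expect_error(fit_linear(rep(2, 5), 1:5), class = "ctda_degenerate_design")
  expect_error(fit_linear(1:4, 1:5), class = "ctda_validation_error")
})

test_that("fit_linear matches a normal-equations oracle on random instances", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:200, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    y <- runif(1, -3, 3) * x + rnorm(1, 0, 5) + rnorm(n)
    f <- fit_linear(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f$r2, o$r2, tolerance = 1e-9)
    expect_true(f$r2 >= 0 && f$r2 <= 1)
  }
})

test_that("slope percent differences use magnitudes and half-away rounding", {
  expect_equal(slope_pct_diff(0.747, 0.6813), 10L)
  expect_equal(slope_pct_diff(0.446, 0.5708), 22L)
  expect_equal(slope_pct_diff(1.3, 1.3), 0L)
  # half-away-from-zero: 11.52 -> 12, not banker's 11
  expect_equal(slope_pct_diff(1.1152, 1), 12L)
  expect_error(slope_pct_diff(1, 0), class = "ctda_validation_error")
  # invariant to sign flips of either argument (magnitude comparison)
  set.seed(7)
  for (i in 1:30) {
    a <- runif(1, -2, 2); r <- runif(1, 0.1, 2)
    base <- slope_pct_diff(a, r, rounded = FALSE)
    expect_equal(slope_pct_diff(-a, r, rounded = FALSE), base)
    expect_equal(slope_pct_diff(a, -r, rounded = FALSE), base)
    expect_equal(slope_pct_diff(-a, -r, rounded = FALSE), base)
  }
})

test_that("mean_abs_pct_diff reports mean to one decimal with range", {
  out <- mean_abs_pct_diff(5)
  expect_equal(out$mean, 5.0)
  expect_equal(c(out$min, out$max), c(5, 5))
  expect_error(mean_abs_pct_diff(numeric(0)), class = "ctda_validation_error")
  set.seed(13)
  for (i in 1:20) {
    d <- runif(sample(1:12, 1), 0, 70)
    out <- mean_abs_pct_diff(d)
    expect_true(out$min <= out$mean_unrounded && out$mean_unrounded <= out$max)
    expect_equal(out$mean, round(mean(d), 1))
  }
})

test_that("build_slope_table recovers injected ground-truth slopes", {
  slopes <- list(chest = c(a = 0.57, b = 1.26),
                 abdomen_pelvis = c(a = 0.68, b = 2.36),
                 head = c(a = 0.30, b = 0.5),
                 neck = c(a = 0.40, b = 0.8),
                 trunk = c(a = 1.06, b = 3.0))
  inj <- inject_linear_sed_structure(cohort_config(n_studies = 400, seed = 31),
                                     slopes, noise_sd = 0.2)
  pts <- inj$points
  pts$region[pts$region == "trunk"] <- "cap"
  pts <- pts[pts$region %in% c("chest", "abdomen_pelvis", "cap"), ]
  pts$ed <- pts$sed * 1.3  # any second metric; slope scales with it
  tab <- build_slope_table(pts)
  chest_ct1 <- tab$table[tab$table$region == "chest" &
                           tab$table$scanner_id == "CT1", ]
  expect_equal(chest_ct1$sed_slope, 0.57, tolerance = 0.03)
  expect_equal(chest_ct1$ed_slope, 0.57 * 1.3, tolerance = 0.04)
  # empty cells stay NA (no abdomen/chest_abdomen points in this cohort)
  empty <- tab$table[tab$table$region == "abdomen", ]
  expect_true(all(is.na(empty$sed_slope)))
  expect_true(all(empty$n == 0))
  # summaries exist and satisfy min <= mean <= max
  expect_true(tab$sed_summary$min <= tab$sed_summary$mean_unrounded)
  expect_true(tab$sed_summary$mean_unrounded <= tab$sed_summary$max)
})

test_that("regions without a reference are flagged and excluded from means", {
  set.seed(5)
  x <- runif(30, 5, 25)
  pts <- data.frame(region = rep(c("chest", "mystery"), each = 15),
                    scanner_id = "CT1", ssde = x,
                    sed = 0.5 * x + rnorm(30, 0, 0.1),
                    ed = 0.7 * x + rnorm(30, 0, 0.1))
  tab <- build_slope_table(pts)
  myst <- tab$table[tab$table$region == "mystery", ]
  expect_true(all(myst$no_reference))
  expect_true(all(is.na(myst$sed_pct_diff)))
  # means computed only from the one referenced cell
  expect_equal(tab$sed_summary$min, tab$sed_summary$max)
})

test_that("feeding the published fitted slopes through the comparison stage
           reproduces the printed percentages and summary means", {
  fits <- reported_fits()
  seg <- martin_segments()
  ref <- stats::setNames(seg$a, seg$region)
  fits$pct <- slope_pct_diff(fits$slope, ref[fits$region])
  fits$pct_raw <- slope_pct_diff(fits$slope, ref[fits$region], rounded = FALSE)
  sed <- fits[fits$metric == "sed", ]
  expect_equal(
    sed$pct[match(c("abdomen_pelvis.CT1", "abdomen_pelvis.CT2", "chest.CT1",
                    "chest.CT2", "cap.CT1", "cap.CT2", "abdomen.CT1",
                    "chest_abdomen.CT1"),
                  paste(sed$region, sed$scanner_id, sep = "."))],
    c(10L, 4L, 4L, 22L, 29L, 13L, 3L, 8L))
  expect_equal(mean_abs_pct_diff(sed$pct_raw)$mean, 11.6)
  ed <- fits[fits$metric == "ed", ]
  expect_equal(round(mean_abs_pct_diff(ed$pct_raw)$mean_unrounded), 28)
})

test_that("slope tables serialise deterministically", {
  set.seed(11)
  x <- runif(40, 5, 25)
  pts <- data.frame(region = "chest", scanner_id = rep(c("CT1", "CT2"), 20),
                    ssde = x, sed = 0.55 * x - 1 + rnorm(40, 0, 0.2),
                    ed = 0.7 * x + rnorm(40, 0, 0.2))
  tab <- build_slope_table(pts)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_slope_table(tab, p1, "json")
  write_slope_table(build_slope_table(pts), p2, "json")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("summarize_box follows the interpolated-quartile, 1.5*IQR convention", {
  b <- summarize_box(1:9)
  expect_equal(c(b$q1, b$median, b$q3), c(3, 5, 7))
  # degenerate constant distribution
  b0 <- summarize_box(rep(4.2, 6))
  expect_equal(c(b0$q1, b0$median, b0$q3, b0$whisker_lo, b0$whisker_hi),
               rep(4.2, 5))
  # far outlier excluded from the whisker by the 1.5*IQR rule
  v <- c(1:9, 100)
  b1 <- summarize_box(v)
  iqr <- b1$q3 - b1$q1
  expect_lte(b1$whisker_hi, b1$q3 + 1.5 * iqr)
  expect_equal(b1$whisker_hi, max(v[v <= b1$q3 + 1.5 * iqr]))
  expect_error(summarize_box(numeric(0)), class = "ctda_validation_error")
  # quartiles match an independent sort-and-interpolate oracle
  set.seed(17)
  for (i in 1:20) {
    v <- rnorm(sample(2:80, 1))
    b <- summarize_box(v)
    expect_equal(b$q1, quartile_oracle(v, 0.25), tolerance = 1e-12)
    expect_equal(b$median, quartile_oracle(v, 0.5), tolerance = 1e-12)
    expect_equal(b$q3, quartile_oracle(v, 0.75), tolerance = 1e-12)
    expect_true(b$q1 <= b$median && b$median <= b$q3)
  }
})
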