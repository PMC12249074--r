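---
title: "Auditing CT dose-monitoring systems: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing CT dose-monitoring systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdoseaudit)
```

## The problem

CT departments increasingly run a dose-monitoring system (DMS) that records,
for every irradiation event (a *series*), the scanner-reported CTDIvol and
dose-length product (DLP), plus geometry such as scan length and patient
effective diameter. From these, risk-related quantities are derived:

* **Effective dose**: $ED = f \cdot DLP$, where $f$ (mSv per mGy·cm) is a
  body-region-specific conversion factor. $f$ is tabulated for a
  reference-sized adult, so ED ignores patient size.
* **Weight-corrected (size-specific) effective dose**:
  $SED = w_{kg} \cdot f \cdot DLP$, with the dimensionless quadratic
  $w_{kg}(w) = c_0 + c_1 w + c_2 w^2$
  ($c_0 = 1.73$, $c_1 = -1.33\times10^{-2}\,\mathrm{kg^{-1}}$,
  $c_2 = 4.04\times10^{-5}\,\mathrm{kg^{-2}}$). $w_{kg}$ is $\approx 1$ at
  70 kg (0.99696), crosses 1 near 69.6 kg, and decreases strictly with
  weight up to its parabola vertex at $-c_1/(2c_2) \approx 164.6$ kg.
* **Size-specific dose estimate**:
  $SSDE = CTDI_{vol} \cdot a_e e^{-b_e D}$, an exponential size conversion
  of CTDIvol by patient diameter $D$ (cm), with phantom-specific
  coefficients (32 cm body: $a_e = 3.704369$, $b_e = 0.03671937$; 16 cm
  head: $a_e = 1.9852$, $b_e = 0.0486$). The conversion factor equals
  exactly 1 at $D = \ln(a_e)/b_e$.
* **SED estimated from SSDE**: Monte Carlo phantom dosimetry yields linear
  relations $SED = a \cdot SSDE - b$ per scanned region, each valid only
  inside a calibrated scan-length window (see `martin_segments()`:
  chest 30–37 cm, abdomen–pelvis 40–50, chest–abdomen–pelvis 62–70,
  abdomen 15–30, chest–abdomen 40–50 cm).

Commercial monitoring systems can store a single, non-editable body region
per study, propagating the region of the *last* series to every earlier
series. For a head-then-chest exam this converts a head DLP (factor
0.0021) into a chest DLP (factor 0.014) — a near-sevenfold inflation of
that series' ED contribution. `emulate_fixed_region()` reproduces exactly
this failure mode so its downstream effect on ED totals and
region-stratified regressions can be quantified.

The audit itself is a region/scanner-stratified comparison: per region and
scanner, OLS fits of SED against SSDE and of ED against SSDE are compared
to the published reference slope as absolute percent differences
$\mathrm{round}\left(\frac{||a_{obs}| - |a_{ref}||}{|a_{ref}|}\times 100\right)$,
and the per-column means of the unrounded differences summarise how much
better SED tracks the reference than ED does.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| conversion factors $f$ | two tables (`aapm_rpt96`, `deak2010` styles) | mSv/(mGy·cm) | the two factor families monitoring systems commonly use; fully overridable, and all worked-example arithmetic supplies factors explicitly |
| trunk factor | mean of chest/abdomen/pelvis factors | mSv/(mGy·cm) | no published trunk factor exists; a trunk acquisition spans all three |
| $w_{kg}$ coefficients | 1.73, −1.33e−2, 4.04e−5 | –, kg⁻¹, kg⁻² | published weight-correction polynomial |
| valid weight range | [20, 200] | kg | outside this the quadratic is extrapolation; out-of-range errors rather than silently evaluating |
| SSDE coefficients | body32 / head16 exponentials | –, cm⁻¹ | published phantom fits; stored in config, never hard-coded in logic |
| effective-diameter guard | (6, 60) | cm | catches mm-vs-cm unit mix-ups at ingest |
| age cutoff | exclude age < 16 | years | reconciles a stated "under 15" exclusion with a cohort whose youngest patient is 16; configurable |
| segment sign convention | `a_x_minus_b` | – | reference segments are published as $a\cdot SSDE - b$; internally fitted lines use $y = ax + b$ |

Percent differences are rounded **half away from zero** (11.52 → 12), the
convention the published slope table follows; summary means are computed
from unrounded differences and reported to one decimal. Both choices are
centralised (`slope_pct_diff()`, `mean_abs_pct_diff()`).

## The abdomen reference slope sign

The published reference table prints the abdomen slope as −0.3793 while
the percent difference reported against it (3%) is only consistent with a
comparison of magnitudes. The shipped segment therefore stores the
magnitude 0.3793 together with a `printed_sign = -1` column, and
`slope_pct_diff()` compares magnitudes, which makes it invariant to sign
flips of either argument. The discrepancy is carried visibly rather than
resolved silently.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces a two-scanner cohort observed through two
views sharing every study and series UID: a region-correct view and a
"commercial" view with the fixed-region failure mode applied. Its stated
world:

* ages truncated normal, 63.3 ± 15.3 y on [16, 104] — the audited cohort's
  reported distribution;
* study-alias mix proportional to the audited counts (head 22051,
  neck 1378, chest 40810, abdomen 14541, pelvis 603);
* scan lengths uniform inside the calibrated per-region windows; head and
  neck, absent from the calibration table, use 12–18 and 15–25 cm
  (typical clinical coverage);
* DLP = CTDIvol × scan length **exactly**, so the DLP identity is testable;
* weight 75 ± 15 kg truncated to [40, 150] — no weight distribution is
  published; this spans $w_{kg}$ from roughly 0.8 to 1.3 so the weight
  correction is exercised on both sides of 1;
* effective diameter affine in weight ($0.2 w + 14$ cm + N(0, 1.5)) for
  body regions and N(17, 1) cm for heads — no diameter model is published;
  an affine-in-weight model preserves the SSDE–SED correlation structure
  the regression analysis relies on;
* CTDIvol lognormal with region-typical medians (head 40, chest 8,
  abdomen–pelvis 12 mGy) — plausible clinical scales; no benchmark value
  depends on them;
* 10% of studies acquire a second, different body region (the misassignment
  substrate); the probability is configurable and the second region always
  differs at series level so the configured rate is the realised rate.

Each study draws from its own RNG stream keyed by (seed, study index):
cohorts are byte-reproducible and extensible without re-drawing earlier
studies.

The generator does **not** emulate scanner physics, tube-current
modulation, protocol naming chaos beyond one canonical name per region, or
attenuation-based water-equivalent diameters. Consequently a green
parameter-recovery or inflation test establishes that the *pipeline
arithmetic and stratification* are correct, not that the package's fitted
slopes would numerically match any particular hospital's. The published
cohort itself (79,383 exams) is not redistributable, so cohort-level
regression values are checked only at the worked-example level: feeding
the published fitted slopes through the comparison stage must reproduce
the printed percent differences and their summary means (11.6 for SED,
about 28 for ED), which the acceptance suite does.

## Numerical choices and degenerate inputs

* OLS via the normal equations as implemented in `stats::lm.fit`; the test
  suite checks it against an independently coded normal-equations oracle
  to 1e-9 relative on hundreds of random instances. Constant-x designs are
  a hard error (slope unidentifiable), as are length mismatches.
* Negative SED from the linear map (possible at small SSDE) is returned
  with a warning and a `negative` attribute, never clamped — clamping
  would bias comparison slopes.
* A missing patient weight raises an error distinct from an out-of-range
  weight: the weight-corrected dose is undefined without it and no default
  is imputed.
* The Deff→Dwater SSDE basis map has no default coefficients; using it
  unconfigured is an error, never a silent identity.
* Box statistics use interpolated (type-7) quartiles with whiskers at the
  most extreme points within 1.5·IQR of the box edges.
* Multi-region study aliases are resolved to the dominant-DLP series'
  region (dose attribution dominates); scouts and bolus-tracking series
  never determine aliases or the fixed region, though they carry their own
  DLP. A trailing-scout switch (`last = "any"`) exposes the alternative
  "last stored series" reading of the fixed-region rule.
* The series region `trunk` has no study-alias counterpart; it maps to the
  study alias `abdomen` by default (its dose-dominant component),
  overridable via `region_map`.

## Known limitations

* Conversion-factor defaults are representative values for the two cited
  factor families, not a reconstruction of any vendor's exact table; all
  benchmark arithmetic supplies its constants explicitly.
* The pipeline's study-level SSDE is the mean of diagnostic-series SSDEs;
  the underlying monitoring systems differ in whether SSDE is stored per
  series or per study, and other aggregations are defensible.
* SED-from-SSDE is only defined inside the calibrated scan-length windows;
  studies falling outside any window are reported as missing, not
  extrapolated.
* One printed percent difference in the published table (chest/CT2/ED,
  21%) disagrees with recomputation from its own printed slopes (20%);
  the package does not special-case it.
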