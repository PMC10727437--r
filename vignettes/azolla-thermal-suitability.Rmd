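---
title: "Thermal performance curves and habitat suitability for Azolla: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal performance curves and habitat suitability for Azolla: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the growth-record
harmonization rules, the hierarchical curve-fitting model and its numerical
treatment, the projection arithmetic, and the design decisions taken where
more than one reasonable choice existed.

## 1. From heterogeneous literature records to one growth table

Studies of temperature-dependent *Azolla* growth report their outcome in
three currencies. `harmonize_records()` reduces all of them to the
relative growth rate (RGR, g g^-1 d^-1):

* **reported** — an RGR given directly is never altered;
* **from masses** — `RGR = ln(Mass2 / Mass1) / (Time2 - Time1)`, the
  exponential-growth definition (the "g/g per day" unit fixes this as a
  log mass *ratio*, not a mass difference);
* **from doubling time** — `RGR = ln(2) / DT`, which round-trips with its
  inverse to machine precision.

The precedence is reported > masses > doubling time, and the chosen path
is recorded per row in `rgr_source`. Additional rules:

* Negative RGR values are **kept**: die-off at temperature extremes is
  biologically real, and although the Room curve cannot predict a negative
  mean, such records still inform the fit through the residual term.
* Temperature entries written as a range (`"20-30"`) or a day/night pair
  (`"30/20"`) are reduced to their arithmetic mean — the model consumes
  one temperature per record — with the original text preserved in
  `conditions`.
* Records carrying extra manipulations (CO2, pH, phosphorus, light) are
  kept by default, with a `keep_manipulated = FALSE` switch to exclude
  them; whether such records should enter a temperature-only fit is a
  judgement call, so the choice is explicit and reversible.
* Replicate observations within a temperature treatment enter the fit
  individually rather than being averaged first; averaging would discard
  the residual-variance information the likelihood uses.
* Rejected rows (no usable growth information, unknown species,
  unparseable temperature) are logged in the table's `filter_log`
  attribute, never silently dropped.

Column headers in source files are mapped through a configurable column
map (a named vector or YAML file) rather than hard-coded, since
compilation spreadsheets rarely share a schema.

## 2. The Room curve and the hierarchical likelihood

The temperature response is the four-parameter piecewise Gaussian

$$P(T) = P_{max} \exp(-a\,(T - T_{opt})^2) \ \ (T \le T_{opt}), \qquad
  P(T) = P_{max} \exp(-b\,(T - T_{opt})^2) \ \ (T > T_{opt})$$

chosen for exactly the properties a growth-rate synthesis needs: unimodal,
asymmetric, defined at all temperatures, and with directly interpretable
parameters. The exponent requires `a` and `b` to carry units of degC^-2
for dimensional consistency, and the package treats them so.

Peak growth rates differ strongly between studies (strains, culture
conditions, experimenter decisions), far more than curve *shape*
plausibly does. The package therefore places a study-level random effect
on **log peak height**: study $j$ grows with peak $P_{max} e^{u_j}$,
$u_j \sim N(0, \sigma_{study})$, keeping the peak positive and making
$\sigma_{study}$ a coefficient of variation on the natural scale.
(Describing the random effect as acting on "the peak height parameter" is
unambiguous only once one notes that the rise-side shape coefficient is a
different parameter; this package anchors the effect to peak height, which
is what between-study variation in maximum growth rate means.) A Gaussian
on the log multiplier is the conventional default; nothing in the data
types constrains the random-effect family further.

Observations are conditionally Gaussian with one shared residual SD
$\sigma_{resid}$ per species fit; reported per-record SDs are carried
through but not used as weights by default (a `use_weights` flag is
reserved in the configuration). The marginal likelihood of study $j$ is

$$L_j = \int N(u; 0, \sigma_{study})
        \prod_i N(y_{ij};\, P_{max} e^{u} s(T_{ij}),\, \sigma_{resid})\, du$$

## 3. Numerical treatment

**Adaptive Gauss–Hermite quadrature.** The integrand above is the product
of a prior of width $\sigma_{study}$ and a conditional likelihood that can
be far narrower (many records, small $\sigma_{resid}$). A fixed Hermite
rule centered at zero then misses the mass entirely, so
`integrated_nll()` first locates each study's integrand mode by 1-D search
and its Laplace scale from the local curvature, and places the (default
21) Hermite nodes shifted to the mode and scaled to that curvature — the
same strategy generalized linear mixed-model fitters use for accurate
marginal likelihoods. Each study's node sum is computed in log space with
a max shift, so the marginal NLL is finite for any finite parameters even
where the raw likelihood underflows. Refining 21 to 61 nodes changes the
reference-fixture NLL by far less than 1e-6, and the rule agrees with a
10^6-draw Monte-Carlo marginalization within Monte-Carlo error (both are
tested). At $\sigma_{study} = 0$ the marginal NLL reduces *exactly* to the
fixed-effects NLL with all offsets zero, which is also tested as an
identity.

**Optimization.** `fit_tpc()` minimizes the integrated NLL over
$(\log P_{max},\, T_{opt},\, \log a,\, \log b,\, \log \sigma_{resid},\,
\log \sigma_{study})$ — logs keep positives positive and make the box
constraints simple — with L-BFGS-B inside bounds
$P_{max} \in (10^{-4}, 2)$ d^-1, $T_{opt} \in (0, 50)$ degC,
$a, b \in (10^{-6}, 1)$, $\sigma \in (10^{-5}, 5)$, motivated by the
5–50 degC span of the underlying experiments and the magnitude of
observed growth rates. Multi-start (default 8) guards against local
optima: the first start is data-anchored ($T_{opt}$ at the temperature of
the largest observed RGR, $P_{max}$ at that RGR), the rest jitter it
deterministically from the configuration seed, and the best converged
start wins, ties broken by lowest NLL then lowest start index. Fits are
bit-reproducible for a fixed seed and empirically stable across seeds.

**Degenerate inputs.** Fitting requires a single species and at least two
distinct temperatures (the inclusion criterion for compiled studies);
violations are errors, not warnings. If no start converges, the error
carries the per-start diagnostics table.

## 4. What the synthetic data emulate — and what they do not

`simulate_records()` inverts the fitting model exactly: draw $u_j$, draw
Gaussian noise around the study-adjusted curve. It therefore tests the
estimator under its own assumptions. The default design — 20 studies of 8
temperatures spanning 5–45 degC, $\sigma_{study} = 0.2$,
$\sigma_{resid} = 0.03$ d^-1 — approximates the scale of a real literature
compilation (a few dozen studies, ~190 records for two species) without
copying one.

`azolla_reference_records()` is a fixed synthetic stand-in for such a
compilation: 282 records across six *Azolla* species, of which 40 belong
to *A. pinnata* and 149 to *A. filiculoides* (189 together), generated at
published-curve parameter values (pinnata 0.25 d^-1 / 24.5 degC /
a 0.0155 / b 0.00344; filiculoides 0.18 d^-1 / 24.5 degC / a 0.005 /
b 0.00495) with the noise levels above. Study temperatures are uniform
draws over 5–45 degC rounded to 0.5 degC, mirroring how real studies pick
their own heterogeneous treatment temperatures. The fixed default seed
makes it a stable reference input, not a random fixture.

What simulation does **not** emulate: digitization error from reading
values off published figures, publication bias across studies,
heteroscedastic residuals, correlation between a study's temperature
choices and its strain, or real shape differences between strains. Passing
recovery tests therefore demonstrate that the estimator is correct and
well-calibrated *under the stated model*, not that the model is right for
any particular real compilation.

A quantitative caveat worth stating: with 10 studies and
$\sigma_{study} = 0.2$, the standard error of the fitted log peak height
is about $0.2/\sqrt{10} \approx 6\%$, and the optimum temperature of a
40-record design carries an SE of several tenths of a degree. Refitting a
*single* synthetic realization therefore recovers the generating
parameters only to within that sampling error — the package's end-to-end
recovery checks are accordingly phrased as medians over 20 replicate
simulations (median $|\hat T_{opt} - T_{opt}| < 1$ degC, median relative
peak error < 10 % at the default 20-study design), which is what a
correctly calibrated estimator should and does achieve.

## 5. Projection arithmetic

`project_suitability()` evaluates the fitted curve at every valid pixel of
a mean-annual-temperature grid; nodata propagates unchanged. Summary
choices, each of which was genuinely open:

* **Unweighted pixel means.** Regional means are plain averages over valid
  pixels; continental summaries of this kind are conventionally reported
  unweighted. `weighted = TRUE` switches on cos(latitude) area weights for
  users on geographic grids who want area-true means.
* **Mask intersection for differences.** A future-minus-current difference
  is defined only where both layers are valid; the difference mask is the
  intersection. By construction
  `mean(difference map) = mean(future) - mean(current)` on the shared
  mask, an identity the tests check to 1e-12.
* **No resampling.** Inputs must share shape and georeferencing;
  misalignment is an error. Silent interpolation of temperature fields is
  a correctness hazard this package refuses.
* **Storage conventions.** Some distributed climate layers store
  degC x 10 as integers; `read_raster(scale_factor = 10)` handles this
  explicitly rather than guessing.
* **Raster format.** I/O uses the ESRI ASCII grid format — a plain-text,
  GDAL-readable single-band raster with explicit nodata sentinel — with an
  optional `.prj` sidecar for the CRS. Report tables round RGR to 3
  decimals and percent change to 2 decimals when written for display;
  all internal arithmetic is double precision.

## 6. Problem sizes used by the shipped checks

The test suite exercises the pipeline at desk scale: quadrature oracles on
a 2-study × 3-record fixture against 10^6 Monte-Carlo draws; projection
exactness on 10 × 10 rasters against brute-force per-pixel recomputation;
recovery medians over 20 replicate 20-study simulations; and full refits
of the 282-record reference compilation. These sizes were chosen so the
whole suite completes in a few minutes while leaving every numerical claim
independently recomputed. Reproducing published *continental* mean growth
rates additionally requires external WorldClim current/RCP rasters and an
Africa mask; with those in hand the check is
`summarize_scenarios(read_raster(...), ...)`, and its agreement depends on
the mask geometry (coastline source, island inclusion), so it is an
optional external validation rather than a shipped test.

## 7. Known limitations

* The Room curve is phenomenological; its parameters describe, not
  explain, thermal physiology, and the curve cannot produce the negative
  growth rates real heat die-offs show (they enter only through the
  residual).
* One shared residual SD per species ignores heteroscedasticity and the
  reported per-record SDs (a weighting hook is reserved).
* The random effect scales the peak only; studies whose *shape* differs
  (strain-level thermal adaptation) are outside the model.
* Projection uses annual mean temperature alone — no seasonality, water
  availability, or photoperiod — so suitability maps are a thermal
  first-order screen, not a species distribution model.
* Confidence intervals are not computed; the fit JSON reserves fields for
  them.
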