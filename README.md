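# azollatpc

Tools for modelling the temperature-dependent growth of *Azolla*, a
nitrogen-fixing aquatic fern used as a rice biofertilizer, and for mapping
where current and future climates can support it.

The package covers the full pipeline:

1. **Harmonize** heterogeneous literature growth records — reported
   relative growth rates (RGR), initial/final biomass pairs, or doubling
   times — into one uniform table of `(study, species, temperature, RGR)`
   observations.
2. **Fit** an asymmetric thermal performance curve (TPC) per species by
   maximum likelihood with a study-level random effect.
3. **Project** the fitted curve pixel-wise onto gridded annual-mean
   temperature rasters to produce habitat-suitability maps and regional
   change summaries under climate scenarios.

## The model

Growth observations are harmonized to the relative growth rate

```
RGR = ln(Mass2 / Mass1) / (Time2 - Time1)        [g g^-1 d^-1]
DT  = ln(2) / RGR                                 [days]
```

and the temperature response is the four-parameter Room curve, a piecewise
Gaussian that is unimodal, asymmetric, and defined at all temperatures:

```
P(T) = Pmax * exp(-a (T - Topt)^2)   for T <= Topt
P(T) = Pmax * exp(-b (T - Topt)^2)   for T >  Topt
```

with peak growth rate `Pmax` (d^-1) at the optimal temperature `Topt`
(degC), rise-side shape `a` and fall-side shape `b` (both > 0). Because
maximum growth rates vary strongly between studies (strains, conditions,
experimenters), study *j* is given a lognormal peak multiplier:
observation *i* in study *j* is modelled as

```
RGR_ij ~ Normal( Pmax * exp(u_j) * shape(T_ij),  sigma_resid ),
u_j    ~ Normal( 0, sigma_study )
```

and `u_j` is integrated out of the likelihood per study by adaptive
Gauss-Hermite quadrature, giving a marginal (integrated) likelihood that
[`fit_tpc()`] maximizes over all six parameters from multiple deterministic
starts.

Habitat suitability at a location is simply `P(T)` evaluated at the
location's mean annual temperature (WorldClim bio1-style layers); regional
summaries are the mean pixel RGR, the mean pixel-wise future-minus-current
difference, and the percent change `100 * mean_diff / current_mean`.

## Worked example

The package ships a fully synthetic stand-in for a literature compilation
(282 records, six species; see `?azolla_reference_records`), so the whole
pipeline runs with no external data:

```r
library(azollatpc)
records <- azolla_reference_records()
pinnata <- filter_species(records, "A_pinnata")
fit <- fit_tpc(pinnata)
fit
#> Room TPC fit (A_pinnata): 40 records, 10 studies
#> Room TPC parameters: p_max = 0.2237 d^-1, t_opt = 25.81 degC, a = 0.01005, b = 0.004431
#>   sigma_resid = 0.03037, sigma_study = 0.3109, logLik = 70.986

current <- simulate_raster(8, 8, "gradient_nodata", t_min = 12, t_max = 42)
future  <- simulate_raster(8, 8, "gradient_nodata", t_min = 12, t_max = 42, offset = 2)
summarize_scenarios(current, list("RCP8.5-2050" = future), fit)
#> # A tibble: 2 x 5
#>   species   scenario    mean_rgr mean_diff pct_change
#>   <chr>     <chr>          <dbl>     <dbl>      <dbl>
#> 1 A_pinnata current        0.164 NA            NA
#> 2 A_pinnata RCP8.5-2050    0.165  0.000772      0.470
```

The fit recovers a peak growth rate near 0.22 d^-1 at an optimum near
26 degC from 40 noisy records spread over 10 simulated studies (the
generating values were 0.25 d^-1 and 24.5 degC — the gap is the sampling
error of a 10-study design). The summary table reads: on this synthetic
temperature grid, a uniform +2 degC warming changes the regional mean
growth rate by +0.00077 d^-1, a +0.47 % change relative to the current
mean.

Real rasters are read with `read_raster()` (ESRI ASCII grid, the
plain-text single-band raster format GIS tools exchange; use
`scale_factor = 10` for layers stored as degC x 10), clipped with
`clip_grid()`, and written with `write_raster()`.

A thin command-line front end over the same functions lives at
`inst/cli/azolla-tpc.R` (subcommands `fit`, `project`, `simulate`).

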