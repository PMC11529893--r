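# phenoasym

Tools for quantifying **asymmetric responses of autumn leaf senescence to
warming versus cooling**, and their propagation into autumn plant
productivity and the terrestrial carbon budget.

## The problem

Autumn leaf senescence dates (LSD) in northern forests track preseason
temperature, but the response need not be symmetric: a 1 °C warm anomaly can
delay senescence by more days than a 1 °C cool anomaly advances it. Whether
this asymmetry exists, how large it is, and what it does to autumn gross
primary productivity (GPP) matters for vegetation models and carbon-cycle
projections — a symmetric model mis-estimates the productivity response to
natural temperature variability by an amount that scales with forest area.

`phenoasym` implements the full analysis chain needed to test this on
satellite-style greenness data and in-situ phenology records:

1. **Senescence-date extraction.** A double-logistic seasonal curve

   *y(t) = a + b (1/(1+e^{c(t−d)}) + 1/(1+e^{e(t−f)}))*,  c < 0, e > 0,

   is fitted per year; LSD is dated both from the second local maximum of
   the curve's second derivative in the second half-year (analytically,
   *f* + ln(2+√3)/*e* for an isolated decline) and from the first downward
   0.5-crossing of the annual amplitude ratio
   *(NDVI − NDVI_min)/(NDVI_max − NDVI_min)*; the two dates are averaged.
   Snow-contaminated observations are replaced by the across-years
   December–February snow-free mean, series are reconstructed with a
   Savitzky–Golay filter, sparse cells (mean annual NDVI < 0.1) are masked,
   and in-situ series are quality-controlled with a median-absolute-deviation
   filter (|LSD − median| > 2.5 × MAD).
2. **Climate drivers.** Cold-degree days CDD = Σ max(T_base − T_daily, 0)
   from July 1 to LSD (T_base ∈ {5, 10, 15} °C); preseason temperature
   mean/SD, precipitation, radiation; frost days (T_min < 0 °C) and a
   min–max frost risk index; preseason mean SPEI; kNDVI = tanh(NDVI²).
3. **Sensitivities.** Per unit, the optimal preseason window (8–120 d, step
   8 d, ending at mean LSD) is chosen by partial correlation of LSD with
   window temperature controlling precipitation and radiation; LSD
   sensitivity to temperature is then estimated by multiple linear
   regression (days/°C) and by ridge regression on min–max-normalized
   anomalies (dimensionless, penalty by generalized cross-validation,
   bootstrap SE).
4. **Asymmetry tests.** Units are classified warming/cooling by the sign of
   their significant autumn (Sep–Nov) temperature trend (plus period-shift
   and 15-year moving-window variants); regime groups are compared by
   Student's t-test, slope ANCOVA, biome random-intercept and location
   random-slope mixed models.
5. **Productivity link.** Autumn productivity (mean kNDVI or accumulated
   Sep–Nov GPP) sensitivities to temperature, their coupling to LSD
   sensitivities, and the carbon-budget bias of assuming symmetry:
   Σ_biome area × |warming − cooling response| × ΔT.

Every stage is exercisable without external data through a fully seeded
synthetic-data generator that plants an asymmetric piecewise-linear LSD
response (defaults: 7.5 days/°C warm side, 3.3 days/°C cool side) together
with coupled climate, greenness, and productivity fields.

## Worked example

```r
library(phenoasym)

cfg <- scenario_config(n_sites = 6, years = c(1999, 2018), seed = 42)
ds  <- generate_dataset(cfg)
ds
#> Synthetic dataset: 6 site(s), 1999-2018 (mixed regime)
#>    120 phenology records, 3000 VI observations

head(extract_lsd(ds$vi[["site1"]]), 3)
#>   cell_id year lsd_derivative lsd_threshold lsd method_flags spread
#> 1   site1 1999            309           295 302         both     14
#> 2   site1 2000            305           290 298         both     15
#> 3   site1 2001            295           275 285         both     20

res <- run_pipeline(list(scenario = list(n_sites = 6, years = c(1999, 2018),
                                         seed = 42), n_boot = 200))
res
#> Pipeline result: 6 site(s), 101 senescence records
#>   LSD sensitivity (MLR): 4.95 (warming) vs 2.46 (cooling) days/degC, p = 0.0734
#>   carbon bias: 0.01229 Pg C yr^-1
```

The per-year table shows the two dating rules (`lsd_derivative` sits later
than `lsd_threshold` by the systematic ln(2+√3)/e offset of the
second-derivative rule) and their average. The pipeline summary shows the
planted asymmetry re-emerging from raw greenness: warming-site senescence
responds about twice as strongly per °C as cooling-site senescence (with
only 6 sites the t-test is underpowered; at 100 sites p < 10⁻¹⁵), and the
bias line is the area-weighted cost of ignoring that difference. A thin CLI
wrapper over the same functions lives at `inst/cli/phenoasym.R`
(`synth` and `run` subcommands).

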