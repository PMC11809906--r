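# cpuecal

Validating capture-per-unit-effort (CPUE) as an index of absolute density,
using a fully enumerated, closed, declining snake population as the
benchmark.

## The problem

For cryptic species — nocturnal arboreal snakes being a canonical case —
managers routinely monitor populations with effort-standardised counts:
snakes seen per kilometre of nocturnal transect walked, or snakes caught
per corrected trap-night. CPUE is cheap and simple, but it is only an
index. It tracks true density faithfully when catchability is constant
(CPUE ∝ N), and it misleads when the index is *hyperstable*
(CPUE ∝ N^β with β < 1, staying high while the population crashes) or
*hyperdeplete* (β > 1). Before CPUE can be used to judge, say, the
progress of an eradication programme, it has to be calibrated against
known abundance — a near-impossible requirement in the field, unless a
closed population has been completely enumerated.

`cpuecal` rebuilds that calibration exercise as a tested pipeline around a
synthetic stand-in for the field system: a 5-ha fenced enclosure (224 ×
224 m), 29 parallel 220-m survey transects covering ≈ 51% of the area
(2-m lanes plus an assumed 1-m detection strip each side), a 169-trap grid
(16-m spacing) that can only catch snakes above 900 mm snout–vent length
(SVL), and a population declining from ≈ 117 to ≈ 15 individuals over 72
months with no immigration or emigration. The package provides:

- **`simulate_population()` / `simulate_visual_surveys()` /
  `simulate_trapping()`** — an individual-based simulator (birth, death,
  linear size growth in mm/day, home transects, a detection model with an
  explicit hyperstability exponent β, size-thresholded trapping with
  optional prey-availability modulation).
- **`backdate_presence()` / `enumerate_monthly()`** — census enumeration:
  each individual's presence is back-dated from its size at first capture
  to the first month its modelled SVL was below 400 mm, and monthly
  abundance is the count of presence intervals covering the month
  (minimum-number-alive logic).
- **`monthly_cpue()` / `build_panel()`** — monthly effort-corrected CPUE
  (ratio of monthly totals) joined to the truth series.
- **`temporal_scheme()` / `apply_temporal_scheme()` /
  `apply_spatial_scheme()` / `rarefy_panel()`** — rarefaction of the full
  record to 15 temporal schemes (monthly/quarterly/biannual × five
  week/night intensities) and evenly spread transect subsets
  (51/25/9/4/2% coverage).
- **`fit_count_glm()` / `predict_density()` / `select_terms()`** —
  Poisson and negative-binomial (NB2) regressions of monthly abundance on
  CPUE with a log-area exposure offset, so coefficients read on the
  density scale: E[density] = exp(β₀ + β₁·CPUE [+ β₂·CPUE²]). Wald 95%
  intervals, Pearson χ² goodness of fit, AIC term selection.
- **`residual_summary()` / `hyperstability_diagnostic()` /
  `scheme_grid_report()`** — accuracy/precision as the mean absolute
  residual between predicted and true density (± 1 SD, pass when
  mean + SD < 5 snakes/ha), plus a low-density bias diagnostic that
  labels a calibration hyperstable/proportional/hyperdeplete.
- **`run_pipeline()`** and a CLI (`inst/cli/cpuecal.R`) tying
  simulate → census → cpue → rarefy → fit → evaluate into a deterministic
  artifact directory.

## Worked example

```r
library(cpuecal)
cfg   <- paper_like_config(seed = 1)        # tuned 72-month preset
ds    <- simulate_dataset(cfg)              # captures + effort + truth
panel <- build_panel(ds$population$truth, ds$captures, ds$effort)
sel   <- select_terms(panel, "total", "visual", "negative_binomial",
                      area = 5.0176)
sel$best
```

```
<cpue_glm_fit> negative_binomial, quadratic CPUE term(s); response 'total' ~ visual CPUE
        term estimate     se ci_lower ci_upper      z
 (Intercept)    0.271 0.0824    0.109    0.433   3.29
        cpue    7.094 0.3787    6.352    7.836  18.73
      cpue^2   -4.504 0.3779   -5.245   -3.763 -11.92
  dispersion (theta): 92.1
  n = 61, logLik = -196.449, AIC = 400.898
  Pearson GOF: X2 = 58.5 on 58 df, p = 0.458
```

The quadratic term wins on AIC (the CPUE–density relationship saturates),
the goodness-of-fit test does not reject the NB distribution, and 61
months of joint effort/truth data enter the fit. Predicting density back
from monthly CPUE and summarising the residual distance:

```r
pred <- predict_density(sel$best, panel$cpue_visual)
pred$month <- panel$month
residual_summary(pred, ds$population$truth)
```

```
<eval_summary> mean |residual| = 1.145, SD = 1.286 (n = 61 months): PASS (mean + SD < 5)
  low-density bias: +0.317 snakes/ha
```

At full spatial coverage the index is an accurate density predictor
(mean error ≈ 1.1 snakes/ha against true densities of 2.4–23.5/ha), and
`hyperstability_diagnostic()` labels the calibration `proportional` —
the +0.32 snakes/ha low-density bias sits inside the ±0.88 practical
equivalence band. Rarefying the same record with
`scheme_grid_report(..., transect_counts = c(29, 14, 5, 2))` shows how
accuracy decays as temporal intensity and especially spatial coverage are
reduced.

## Layout

```
R/                 simulator, census, CPUE, rarefaction, GLMs, evaluation, pipeline
inst/cli/          cpuecal.R command-line driver (simulate|census|cpue|rarefy|fit|evaluate|run)
tests/testthat/    unit + property tests; test-acceptance.R holds the acceptance criteria
scripts/           acceptance.R (acceptance report)
vignettes/         methods vignette (model, assumptions, design choices)
```
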