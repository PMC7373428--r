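# ferroscale

Quantitative machinery for studying ferroptosis-linked aging in
*Caenorhabditis elegans* — and, more generally, for any study that asks
whether a lifespan intervention *stretches time* or changes the shape of
aging, and that measures in vivo iron by synchrotron imaging.

Ferrous iron (Fe²⁺) accumulates in aging nematodes while glutathione
falls, priming cells for ferroptosis; interventions that block this death
pathway extend lifespan in ways that are *not* a simple temporal
rescaling of the survival distribution. Testing that claim, and
quantifying the iron biology underneath it, requires three pieces of
statistical machinery that this package implements as a tested, reusable
library:

1. **Temporal-rescaling survival analysis.** Lifespans are modelled by a
   Weibull baseline hazard with per-animal Gamma frailty
   (mean 1, variance σ²), whose marginal survival is
   S(t) = (1 + σ²(t/b)ᵏ)^(−1/σ²). Interventions enter as per-arm
   departures Δlog b (pure rescaling, factor λ), Δlog k (shape) and
   Δlog σ² (frailty heterogeneity), selected by likelihood-ratio tests
   and pooled across replicates by inverse-variance (fixed-effect) or
   DerSimonian–Laird (random-effect) meta-analysis. Departure from pure
   rescaling is tested nonparametrically: a Buckley–James accelerated
   failure time fit removes arm location effects from log-lifetimes, and
   a censoring-aware two-sample Kolmogorov–Smirnov statistic on the
   residuals is referred to a permutation null that refits the AFT model
   per relabelling. Kaplan–Meier curves, log-rank tests and smoothed
   hazard-rate curves round out the suite.
2. **φXANES iron speciation.** Energy stacks of Fe X-ray fluorescence
   across the K-edge (the published 106-point scan protocol ships as the
   default grid) are energy-calibrated against an iron-foil derivative
   peak at 7112.0 eV, aligned by cross-correlation of the calcium
   channel, reduced to edge-jump-normalized ROI spectra, and fitted in
   the pre-edge window with an arctangent rising-edge baseline plus a
   single Gaussian for the 1s→3d feature. The ferrous fraction is
   estimated either from the pre-edge centroid or from the relative
   intensity of 1s→4s / 1s→4p first-derivative features, both inverted
   against endmember calibrations, with parametric-bootstrap CIs.
3. **XFM elemental quantification.** Worms are segmented from Compton
   scatter maps by Otsu thresholding and 8-connected labelling with a
   10,000-pixel minimum size, backgrounds are suppressed at the Currie
   critical level L_C = z₁₋α√(2·B̄), foil standards calibrate counts to
   areal density (pg µm⁻²), and each animal is reported as mean areal
   density, area and total iron mass (pg).

A synthetic-data module (`gen_lifespan`, `gen_xanes_stack`,
`gen_xfm_scene`, `gen_dose_response`) generates all of these inputs with
known ground truth, so the full pipeline runs and is tested with no
external data. Dose–response (Hill/LD50), Wilson intervals, N−1
chi-square, two-proportion z, ANOVA/Kruskal–Wallis with Tukey / Šidák /
Dunn–Šidák post hocs and the D'Agostino–Pearson normality gate cover the
cohort statistics such studies report.

## Worked example: is a lifespan extension a pure stretching of time?

```r
library(ferroscale)

cfg    <- default_lifespan_config(seed = 1)   # 3 arms x 8 replicates, 25 C
cohort <- gen_lifespan(cfg)
rep1   <- subset(as.data.frame(cohort), replicate == 1)

km_curve(rep1$day[rep1$arm == "control"], rep1$event[rep1$arm == "control"])
#> <km_curve> n = 90, events = 90, median = 8.486866
logrank(rep1)
#> log-rank chisq = 167.7 on 2 df, p = 3.84e-37

bj <- fit_buckley_james(rep1)
bj
#> <bj_fit> Buckley-James AFT (log-time scale)
#> (Intercept)        lip1         sih
#>      2.0898      0.4240      0.6145
#> scale 0.3201; converged after 0 iteration(s)

ks_rescaling_test(bj, n_perm = 200, seed = 2)
#> <rescaling_test> D = 0.1444, permutation p = 0.1393 (200 permutations)

lrt_select(rep1)
#> <lrt_selection> best model: +shape
#>           from       to df   lrt      p
#> 1 scaling-only   +shape  2 6.955 0.0309
#> 2 scaling-only +frailty  2 4.039 0.1330
#> 3       +shape     full  2 0.114 0.9440
```

The AFT coefficients are log time-scale factors: exp(0.61) ≈ 1.85 says
the chelator arm lives ~85 % longer in this replicate. A single replicate
of 90 animals per arm rarely rejects pure rescaling on its own
(p = 0.14 here); pooling the eight replicate-level permutation p-values
with `fisher_combine()` rejects it decisively (p < 0.01 across seeds),
and model selection attributes the departure to a shape change — the
"squaring" of the survival curve — rather than to rescaling alone.

Speciation works the same way end to end:

```r
cal   <- speciation_calibration()
n     <- 24
cfg   <- xanes_sim_config(fe2_fraction_map = matrix(0.3, n, n),
                          iron_density_map = {d <- matrix(0, n, n)
                                              d[7:18, 7:18] <- 1; d},
                          counts_scale = 1e4, seed = 7)
stack <- align_stack(gen_xanes_stack(cfg))
sp    <- extract_normalized_spectrum(stack, cfg$iron_density_map > 0)
fit_pre_edge(sp)
#> <preedge_fit> centroid 7113.185 eV (95% CI 7113.138-7113.231), width 1.04 eV, residual rms 2.11e-03
estimate_fe2_fraction(fit_pre_edge(sp), sp, cal, mode = "centroid",
                      n_boot = 200, seed = 1)
#> Fe2+ fraction 0.300 (95% CI 0.296-0.304)
```

A planted ferrous fraction of 0.30 — the level aged animals reach — is
recovered to three decimals at realistic counts.

## Package layout

- `R/simulate-*.R` — ground-truth generators (lifespan, XANES stacks, XFM
  scenes, dose–response)
- `R/surv-*.R`, `R/meta.R` — Kaplan–Meier/log-rank/hazard, Buckley–James,
  rescaling test, Weibull–Gamma frailty models, LRT selection, GOF,
  meta-analysis
- `R/energy-grid.R`, `R/xanes-*.R` — scan grid, alignment, calibration,
  normalization, pre-edge fitting, speciation
- `R/xfm-quant.R` — segmentation, Currie thresholding, foil calibration,
  per-worm quantification
- `R/cohort-stats.R` — dose–response and cross-sectional statistics
- `R/pipeline.R` — `run_pipeline()` orchestration and validated I/O
- `vignettes/ferroscale-methods.Rmd` — models, assumptions, parameter
  choices and limitations
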