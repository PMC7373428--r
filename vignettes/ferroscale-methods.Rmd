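---
title: "Models and methods behind ferroscale"
author: "ferroscale maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ferroscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroscale)
```

`ferroscale` implements three quantitative pipelines used in studies of
ferroptosis-driven aging in *C. elegans* — in vivo iron speciation from
energy-resolved fluorescence image stacks, per-animal iron quantification
from X-ray fluorescence microscopy (XFM) maps, and a survival-analysis
suite built around the question of whether a lifespan intervention acts by
*temporal rescaling* — together with the cohort statistics that accompany
such studies and a synthetic-data module that makes every stage testable
without beamtime or a worm lab. This vignette describes the models, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## 1. Survival analysis

### The Weibull–Gamma frailty model

Lifespans are modelled with a Weibull baseline hazard and a per-animal
multiplicative frailty $z \sim \Gamma(\text{mean }1, \text{var }\sigma^2)$:
conditional hazard $z\,(k/b)(t/b)^{k-1}$. Integrating $z$ out gives the
marginal law implemented in `sweibgamma()` / `dweibgamma()`:

$$S(t) = \bigl(1 + \sigma^2 (t/b)^k\bigr)^{-1/\sigma^2},\qquad
  f(t) = \frac{k}{b}\Bigl(\frac{t}{b}\Bigr)^{k-1}
         \bigl(1 + \sigma^2 (t/b)^k\bigr)^{-1/\sigma^2-1}.$$

Frailty heterogeneity makes the *population* hazard decelerate late in
life even though every individual hazard rises — the mechanism behind
crossing survival curves and the single most important failure mode of the
pure temporal-rescaling description. As $\sigma^2 \to 0$ the law reduces
continuously to Weibull; internally $\sigma^2$ is floored at $10^{-8}$ and
the `log1p` form keeps the limit numerically continuous (verified by a
continuity test across the floor).

`fit_weibull_gamma()` maximizes the marginal likelihood (events contribute
$\log f$, right-censored animals $\log S$) with all parameters on the log
scale, which gives positivity without constraints and lets per-arm
departures read directly as log-ratios: every non-reference arm carries a
scale departure $\Delta\log b$ (that is temporal rescaling), and
optionally $\Delta\log k$ (shape) and $\Delta\log\sigma^2$ (frailty)
departures. Three optimizer starts are used; one sits near the Weibull
limit ($\sigma^2 = 10^{-7}$) because the $(\log k, \log\sigma^2)$
trade-off direction is flat near frailty-free data and a single start can
otherwise stall at a slightly frailty-inflated solution.
`lrt_select()` does forward likelihood-ratio selection from the
scaling-only model at $\alpha = 0.05$, with ties broken toward fewer
parameters.

### Testing for departure from temporal rescaling

Under pure rescaling an intervention multiplies every lifespan by a single
factor $\lambda$, so log-lifetimes differ between arms by a location shift
only. `fit_buckley_james()` fits the accelerated-failure-time location
model by the Buckley–James method: censored log-times are replaced by
their conditional expectations under the Kaplan–Meier estimate of the
residual distribution and least squares is iterated. With no censoring the
procedure *is* ordinary least squares (tested to machine precision); with
censoring the iteration can land on a limit cycle rather than a fixed
point, which the implementation detects for any cycle period and resolves
by averaging the cycle, flagged in the fit.

`ks_rescaling_test()` then compares the arm-wise residual distributions
with a censoring-aware two-sample Kolmogorov–Smirnov statistic: the
sup-distance between Kaplan–Meier CDF estimates, restricted for each arm
pair to the region where both CDFs are estimable (beyond the smaller arm's
last event residual one curve is flat by construction, and unequal
censoring would otherwise inflate the distance artificially). Because the
AFT coefficients are estimated, the permutation null refits the AFT model
for every relabelling — this is the "modified" aspect of the test; the
exact construction of the statistic was an open design point and this
package's choice is the refit-per-permutation null. Calibration is part of
the acceptance suite: the empirical size at $\alpha = 0.05$ over 500
pure-scaling simulations must sit inside the binomial interval, and power
against a shape departure of $\Delta\log k = \log 2$ at 300 animals per
arm must exceed 0.8. Replicate-level p-values are pooled with Fisher's
method (the pooling rule for replicate-specific tests was unstated and is
this package's choice). Pure *frailty* departures of moderate size
($\Delta\log\sigma^2 \approx -1$) sit near the edge of this test's
sensitivity at 90 animals per arm — a real limitation worth knowing when
interpreting a non-rejection.

`gof_chisq()` maps event times through the fitted arm-specific CDF and
bins the resulting (ideally uniform) values into equal-probability bins,
merging until every expected count is at least 5; df is bins − 1 with no
subtraction for estimated parameters, because the intended use evaluates
externally supplied (for example meta-analytic) parameter values against
each replicate. `meta_combine()` implements fixed-effect inverse-variance
pooling in closed form and DerSimonian–Laird random effects;
`hazard_curve()` estimates the life-table hazard (events per person-day in
unit intervals) with exposure-weighted Gaussian-kernel smoothing and a
bootstrap CI.

### What the lifespan generator emulates

`gen_lifespan()` inverts the frailty model exactly: $T =
b\lambda e^{u_r}(E/z)^{1/k}$ with $E \sim \text{Exp}(1)$, per-animal
frailty $z$, and a per-replicate log-scale offset $u_r$ shared by all arms
of a replicate (frailty is per animal, never per replicate; replicate
effects enter only through the scale). The default study configuration
(`default_lifespan_config()`) mirrors a three-arm intervention experiment
at 25 °C: control with shape 4, scale 8.5 days (median ≈ 8 days, within
the 7–9 day range such controls show), frailty variance 0.5; a
late-life-acting arm with $\lambda = 1.7$; and a chelation arm with
$\lambda = 2.0$ plus a shape increase $\Delta\log k = \log 1.4$ — the
"squaring" of the survival curve such treatments produce — and both
treatment arms with $\Delta\log\sigma^2 = -1$, i.e. less unobserved
heterogeneity than controls. Eight replicates of 90 animals per arm with
a 0.05 SD replicate offset reproduce the magnitude of between-replicate
median variation such experiments report. Death times are continuous by
default; `discretize = TRUE` rounds up to whole scoring days to mimic
1-day scoring visits (the paper-style alternative of interval scoring at
1–3-day gaps is approximated by this daily discretization plus midpoint
behaviour in the estimators). What the generator does *not* emulate:
bacterial-diet effects, temperature kinetics (temperature enters only as
a pure scaling factor), and non-proportional frailty mechanisms; passing
tests therefore show estimator correctness under the stated model, not
robustness to every failure of it in real cohorts.

## 2. XANES speciation

### The stack and its geometry

A fluorescence-detected XANES image stack holds one Fe-fluorescence frame
per incident energy across the Fe K-edge (7112 eV). The energy grid
builder reproduces the published scan protocol (5×20 eV, 5×1 eV, 75×0.4 eV,
15×2 eV, 1×240 eV, 5×5 eV segments from 7000 eV). The printed table is
internally inconsistent — the step counts imply 107 points while the text
declares 106, and the final segment's span disagrees with its steps — so
`build_energy_grid()` trusts the step counts, truncates to the declared
106 points, and records both discrepancies in the object rather than
resolving them silently.

`calibrate_energy_axis()` implements the foil convention: the first local
maximum of the derivative spectrum of a metallic iron foil defines
7112.0 eV, with the derivative taken on a spline interpolant sampled at
0.02 eV to beat the sparse grid. `align_stack()` recovers frame-to-frame
drifts by integer-pixel normalized cross-correlation of the calcium
channel (essentially constant through the energy series) against the
first frame; sub-pixel interpolation is deliberately avoided because it
smears sparse counts. Frames whose best shift saturates the search bound
are flagged and their energies marked missing in extracted spectra.

### Normalization and the pre-edge fit

`extract_normalized_spectrum()` sums ROI counts per energy and performs
edge-jump normalization: a line fitted below 7105 eV is subtracted and a
linear post-edge fit (≥ 7135 eV) scales the jump to one pointwise. The
result is invariant to rescaling the raw counts, so speciation never
depends on iron abundance.

`fit_pre_edge()` models the rising edge inside the 7108–7118 eV window as
the tail of an arctangent fitted to the window flanks only (three
parameters, stable on a 0.4 eV grid, and the natural shape for a
monochromator-broadened edge), then fits a single Gaussian to the
baseline-subtracted residual; the pre-edge centroid is the Gaussian
center with a Wald 95 % CI from the fit covariance. One Gaussian is used
for the whole 1s→3d envelope by design; resolving its crystal-field
components is out of scope.

### From centroid to ferrous fraction

The centroid shifts up with oxidation state, from about 7112.1 eV for
ferrous to about 7113.5 eV for ferric reference compounds (these
defaults are configurable; the choice follows the pre-edge literature
convention since no in-house standards ship with the package). The naive
linear inversion $f = (c_3 - \hat c)/(c_3 - c_2)$ is biased by up to
±0.075 in $f$, because a single-Gaussian fit of a two-component envelope
is pulled toward the dominant component more than linearly.
`speciation_calibration()` therefore precomputes the centroid-versus-
fraction response on model endmember mixtures and
`estimate_fe2_fraction()` inverts through that curve by monotone
interpolation — the same philosophy as derivative mode, where feature
intensities integrated over the 1s→4s (7117–7123 eV) and 1s→4p
(7125–7131 eV) first-derivative windows are inverted exactly against
endmember-derived intensities. The window defaults were set against the
generator endmembers since no published windows exist. Both modes clip to
[0, 1] with a flag rather than erroring, because noise can push a linear
inversion outside the simplex. Confidence intervals come from a
parametric bootstrap over Poisson noise of the ROI counts (200 resamples
by default); group contrasts in `compare_groups()` bootstrap over
animals, which is the defensible reading of per-group CIs when the
animal, not the pixel, is the experimental unit.

Both estimation modes are validated only against the synthetic endmember
model: with real beamline standards the calibration object should be
rebuilt from measured endmember spectra. This is a deliberate limitation,
not an oversight.

## 3. XFM quantification

Compton-scattered intensity is brighter over specimen mass, so
`segment_compton()` thresholds the Compton channel with Otsu's
deterministic two-class variance-maximizing threshold (the histogram
"clustering" step admits many algorithms; this one is parameter-free and
reproducible), labels 8-connected components (4-connectivity fragments
thin curved bodies), and discards components under 10 000 pixels —
regions too small to reflect whole-animal content. Partial animals at
scene edges are kept if large enough. A scene with no separable
foreground yields an empty ROI set with a warning status, never an
exception.

`currie_threshold()` computes the Currie critical level in the
paired-blank convention, $L_C = z_{1-\alpha}\sqrt{2\bar B}$ (the classical
$2.33\sqrt{\bar B}$ at $\alpha = 0.05$). Note the convention carefully:
the $\sqrt 2$ arises because the decision is about a *difference* of two
Poisson counts (sample minus blank), so the advertised false-detection
rate $\approx \alpha$ applies to paired differences; against a
well-estimated mean background the same threshold is conservative
(roughly 1 % at $\bar B = 50$). The acceptance property measures the rate
in the paired sense. `quantify_rois()` subtracts the mean background,
zeroes net values at or below $L_C$, applies the foil calibration factor
(`foil_calibration()`, zero-intercept least squares over standards, with
the µg cm⁻² → pg µm⁻² conversion ×0.01 centralized and tested), and
reports per-ROI mean areal density, area and total mass; the identity
mass = density × area is exact by construction. One caveat the tests make
explicit: sub-threshold animal pixels land in the empirical background
region (no guard band is used, per the default design), inflating the
background mean by a fraction of a count and biasing recovered mass by
about −1 % at default conditions; the quantification contract is
therefore verified on the exact planted footprint with an uncontaminated
background region.

The scene generator plants elliptical "worms" (disjoint by construction —
overlap would make per-worm truth ambiguous) with uniform areal
densities, linear density→counts gains and Poisson noise everywhere; no
detector response, self-absorption or matrix effects are simulated, which
is exactly the boundary where an upstream spectral-deconvolution engine
would sit in a real pipeline. The default detector gain (1000 counts per
pg µm⁻²) puts the default worm signal near 20 counts/pixel over a
2-count background — a regime where per-pixel detection is comfortable,
consistent with quantitative XFM of these specimens.

## 4. Dose–response and cohort statistics

Lethality follows a Hill curve on linear dose, $P(d) = d^h/(d^h +
\mathrm{LD50}^h)$, fitted by binomial maximum likelihood on
$(\log \mathrm{LD50}, \log h)$ with optional free asymptotes (fixed at
0/1 by default; which the original fits used was unstated, so both are
available). The generator's default LD50 of 10 mM at day 4 of adulthood
anchors "about half lethality at 10 mM", and an age-sensitivity term
shifts log-LD50 per day of age so older cohorts are more sensitive.

The remaining cohort statistics are deliberately thin, auditable wrappers:
Wilson score intervals in closed form; the N−1 chi-square as Pearson ×
(N−1)/N; the pooled-variance two-proportion z-test without continuity
correction (the variant behind published Z values is unstated, so the
choice is documented to make discrepancies attributable); one-way ANOVA
via `stats::aov` with Tukey HSD or Šidák-adjusted pooled-t pairwise
comparisons; tie-corrected Kruskal–Wallis via `stats::kruskal.test` with
Dunn's rank-based pairwise z-tests under Šidák adjustment ("Dunn–Šidák");
the D'Agostino–Pearson $K^2$ omnibus normality gate implemented from the
standard skewness and kurtosis transforms (no installed package provides
it); and OLS regression through `stats::lm`.

## 5. Reproducibility and problem sizes

Every generator takes an explicit integer seed and seeds R's global
Mersenne–Twister itself; identical configurations are bit-reproducible,
and there is no hidden RNG state. `run_pipeline()` records the seed,
package version and per-stage status in a machine-readable report, and
fails a stage without aborting the rest.

The test and acceptance workloads use problem sizes chosen to make each
statistical claim decidable without waste: 500 simulations for the size
of the rescaling test (binomial CI half-width ≈ 0.019 around 0.05), 100
for its power, 20 seeds × 2000 animals/arm for frailty-parameter
recovery (relative SE of the mean under 2 %), 24×24-pixel stacks at 10⁴
expected counts for speciation recovery, and one 300×400 scene per seed
for segmentation. Permutation counts of 100–200 bound the p-value
granularity well below the decision thresholds involved.

## Known limitations

- The rescaling test's permutation null assumes exchangeable residuals;
  under heavy, strongly arm-dependent censoring its size is maintained by
  the common-support restriction but power degrades.
- Interval-censored scoring is handled by daily discretization /
  midpoint-style imputation, not an exact interval likelihood.
- Speciation accuracy is demonstrated against the synthetic endmember
  family; real-standard calibration is the user's responsibility.
- GOF df convention (bins − 1) is only correct when evaluated parameters
  are not fitted to the same data.
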