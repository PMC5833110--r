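---
title: "Semi-parametric fertility modelling over age, SES and time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parametric fertility modelling over age, SES and time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertgp)
```

## The model

`fertgp` estimates age-specific fertility rates from woman-year census
records — one row per woman per census round, with her midyear age, a
continuous socio-economic status (SES) index, and a binary live-birth
indicator $Y_i$. The probability of a live birth is modelled as a Gamma
density in age whose parameters vary with the other covariates
$\mathbf{x} = (\text{SES}, \text{year})$:

$$
p(a; \mathbf{x}) \;=\; \Pr(Y = 1 \mid a, \mathbf{x}) \;=\;
\frac{a^{\alpha(\mathbf{x}) - 1}\, e^{-a/\beta(\mathbf{x})}}
     {\Gamma(\alpha(\mathbf{x}))\, \beta(\mathbf{x})^{\alpha(\mathbf{x})}},
$$

clamped to $[0, 1)$ so that it can act as a Bernoulli success probability
(a Gamma density exceeds one for small scale parameters; clamped
observations are counted and excluded from likelihood gradients). The Gamma
curve captures the well-established skewed hill shape of fertility over
age, with a single mode at $(\alpha - 1)\beta$.

No parametric form is assumed for $\alpha(\mathbf{x})$ and
$\beta(\mathbf{x})$. Instead they are estimated in two stages:

1. **Per-slice Gamma fits.** Observations are quantile-binned in age and
   SES (year stays discrete); within each (SES-bin × year) slice,
   $(\alpha, \beta)$ maximise the binomial log-likelihood
   $\sum_c \left[ b_c \log p_c + (t_c - b_c)\log(1 - p_c) \right]$ over the
   slice's age cells, where $p_c$ is the Gamma rate at the cell's age
   midpoint and $t_c, b_c$ are its trials and births.
2. **Gaussian-process smoothing.** The per-slice estimates are smoothed
   over $(\text{SES}, \text{year})$ by Gaussian process regression with the
   squared-exponential kernel
   $$
   K(\mathbf{x}_i, \mathbf{x}_j) = \sigma_f^2
   \exp\!\left[-\tfrac12 (\mathbf{x}_i - \mathbf{x}_j)^\top M
   (\mathbf{x}_i - \mathbf{x}_j)\right] + \sigma_n^2 \delta_{ij},
   \qquad M = \mathrm{diag}(\mathbf{l})^{-2},
   $$
   one lengthscale per covariate. Predictions use the posterior mean
   $\mu = K(X^*, X) K(X, X)^{-1} \mathbf{y}$ (computed through a Cholesky
   factorisation, never an explicit inverse); the posterior covariance
   follows the standard conjugate formula. Hyperparameters
   $(\sigma_f^2, \sigma_n^2, \mathbf{l})$ maximise the log marginal
   likelihood, plus a Gamma(shape 6, scale 0.25) log-prior on the SES
   lengthscale (mode $5 \times 0.25 = 1.25$ SES units) that guards the SES
   relationship against overfitting. Other hyperparameters carry improper
   flat priors on the log scale. Optimisation runs in log-space with
   analytic gradients from ten seeded restarts drawn log-uniformly over
   $[10^{-2}, 10^2]$ times data-derived scales; GP targets are centred
   internally and the mean added back at prediction.

Prediction composes the two stages:
`predict_fertility(model, a, ses, year)` evaluates the Gamma curve at the
GP-smoothed parameters.

## Which coordinates the GPs smooth

The two GPs are independent, and the choice of coordinates matters more
than it first appears. The per-slice MLE errors of $\log\hat\alpha$ and
$\log\hat\beta$ are almost perfectly negatively correlated: a slice
determines the *mean age* of its fertility curve,
$\mu = \alpha\beta$, precisely (its log has per-slice errors of order
$0.03$ at a few dozen births), while the *width* direction is poorly
identified (errors of order $0.4$ on each log-parameter individually).
Smoothing $\log\hat\alpha$ and $\log\hat\beta$ independently lets the
large width-direction noise leak into the precisely measured mean-age
direction, and the far flanks of the rate curve — which respond
exponentially to a shift in the mean age — degrade badly.

The default (`gp_parameterisation = "mean-shape"`) therefore smooths the
near-orthogonal coordinates $\log(\alpha\beta)$ and $\log\alpha$: each GP
then sees a noise level commensurate with its own signal, and the
architecture is otherwise unchanged (two independent GPs, same kernel,
same priors). `"shape-scale"` retains direct smoothing of $\log\alpha$
and $\log\beta$ for comparison. Both guarantee positive predicted
parameters because smoothing happens on log scales.

## Small-sample bias of the slice fits

The shape MLE of a Gamma model from $k$ effective observations (here the
birth count of a slice) is biased upward, by roughly $3/k$ on the log
scale — at census scale with 125 age and 25 SES quantiles a slice holds
only a dozen or so births, so the bias is material and GP smoothing
averages it rather than removing it. Three options are available through
`slice_bias_correct`:

* `"calibrate"` (default): simulate replicate birth counts from each
  fitted slice at its own cell layout, refit, and measure the mean
  log-scale displacement of the ensemble; iterating twice solves the fixed
  point $\hat\theta = \theta + b(\theta)$. Because the correction is an
  ensemble average over all slices, its Monte-Carlo error is small, and it
  adapts automatically to the slice layout and truncation of the observed
  age range.
* `"analytic"`: the first-order correction
  $\tilde\alpha = \hat\alpha\, k/(k+3)$, preserving the fitted mean
  $\hat\alpha\hat\beta$.
* `"none"`: smooth the raw MLEs.

Slices are excluded from GP training (with a warning) when they fail to
converge, hold fewer than `min_slice_trials` woman-years (default 50), or
produce a fitted mode outside the observed age support — the signature of
a fit driven by a handful of births.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `age_quantiles`, `ses_quantiles` | 125, 25 | quantile-bin counts, suited to census-scale tables; re-select per dataset with `select_model()` |
| `folds` | 10 | cross-validation folds |
| `level` | 0.05 | familywise significance level for goodness-of-fit rejection |
| `bootstrap_reps` | 1000 | parametric bootstrap replicates |
| `ses_prior` | Gamma(6, 0.25) | smoothing prior on the SES lengthscale |
| `min_slice_trials` | 50 | minimum woman-years for a slice to enter GP training |
| `gamma_restarts`, `gp_restarts` | 5, 10 | optimiser restarts |
| `gp_parameterisation` | `"mean-shape"` | GP smoothing coordinates (above) |
| `slice_bias_correct` | `"calibrate"` | slice bias handling (above) |

Quantile counts should scale with the data: at $2 \times 10^4$ woman-years
the default $125 \times 25$ layout leaves only a few births per slice, and
a coarser layout (e.g. 60 × 6) is appropriate. Choosing among such layouts
is exactly the job of `select_model()`, which scores candidates by
ten-fold cross-validated Brier score
$S_B = \frac{1}{N}\sum_i (Y_i - p_i)^2$, rejects candidates whose
Kolmogorov–Smirnov goodness of fit falls below the Bonferroni-corrected
threshold `level / n_candidates`, and picks the minimum mean Brier among
the survivors.

### The KS construction

Comparing two fitted rate curves is not a textbook KS setting. The package
compares the *marginal age distribution of births*: the empirical
distribution of ages at which births occurred, against the model-implied
distribution obtained by summing predicted rates over all observed
covariate rows on an age grid and normalising. The statistic is the sup
distance between the two CDFs on the grid, with the asymptotic one-sample
p-value at $n$ = number of births. Because the model is fitted to the same
data, the test is conservative; its empirical size on correctly specified
synthetic data is checked in the test suite.

## Uncertainty

`parametric_bootstrap()` simulates $Y^*_i \sim
\text{Bernoulli}(\hat p(a_i, \mathbf{x}_i))$ at the observed covariates,
refits the entire pipeline (slice fits, bias calibration and GP
hyperparameter re-optimisation), evaluates the refitted curve on an
evaluation grid, and reports pointwise 2.5/25/50/75/97.5 percentiles
across replicates. Refits warm-start the GP optimiser at the original fit
with a reduced restart count (`bootstrap_gp_restarts`, default 2) — the
refit landscape is a perturbation of the original, so the full restart
sweep would spend most of its time rediscovering the same optimum. A
cheaper `mode = "gp-draw"` alternative draws parameter surfaces from the
fitted GP posteriors without refitting; it omits slice-fit uncertainty and
yields narrower bands.

## The synthetic-data generator

Real surveillance data of this kind are not publicly deposited, so the
generator stands in for them with known ground truth. Its defaults emulate
the study conditions: six census rounds in the odd years 2001–2011 with
37,440 woman-years each (224,640 in total), ages 10–55, SES 1–4, and a
Bernoulli birth indicator whose success probability follows the Gamma
curve with shape $\alpha(\mathbf{x}) = 66 + 1.2(\text{SES} - 2.5) +
0.35(\text{year} - 2006)/2$ and scale $\beta = 0.42$ years. That places
the peak age between roughly 26 and 28.5 and the peak rate near
0.115–0.120, matching the magnitudes of the published empirical rate
tables for such populations (about 0.10–0.13 for ages 20–30); note that a
Gamma *density* with that peak height and location is necessarily narrow,
since its peak value is approximately $0.4 / (\sqrt\alpha\, \beta)$. The
SES dependence is weak and the year trend mild, consistent with the
near-constant SES pattern such studies report.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* age and SES marginals are uniform — the real population pyramid is not
  modelled (both samplers are configurable on the truth object);
* women are redrawn independently each year: no longitudinal correlation,
  migration, mortality or household structure;
* the SES index is a given continuous covariate; its construction from
  household assets is out of scope;
* an optional refugee stratum is mixed in at a configurable fraction
  (default 0.3), by default with identical rates, or from an independent
  truth object to emulate stratified analyses.

## Numerical choices

* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7); bin midpoints are interval centres; the last
  interval is closed; tied edges merge with a warning.
* Rates are clamped to $[0, 1 - 10^{-9}]$ before Bernoulli draws and
  inside likelihoods; clamped cells contribute zero gradient.
* Gamma slice fits run BFGS on $(\log\alpha, \log\beta)$ with analytic
  gradients, a method-of-moments initialiser on the birth-weighted age
  distribution, and five seeded log-normal restarts; relative objective
  tolerance $10^{-8}$.
* GP factorisations add jitter escalating from $10^{-10}$ to $10^{-6}$
  before failing with condition diagnostics.
* Covariates enter the GP in raw units (SES index points, calendar years);
  no standardisation. Year is a continuous GP dimension with its own
  unpenalised lengthscale, so per-year displays come from slicing a single
  model; `per_year_gp = TRUE` fits separate per-year GPs instead for
  sensitivity checks.
* Cross-validation partitions woman-years (the observation unit);
  `cv_group_by_woman = TRUE` keeps each woman's rows in one fold since
  repeat observations of a woman are not independent.
* All randomness flows from explicit seeds through a splitmix-style
  derivation, and user RNG state is restored; identical configuration and
  seed reproduce results bit for bit.

## Problem sizes used in validation

The test suite validates end-to-end recovery on three independent
populations of $10^5$ woman-years (surface errors are assessed on a grid
spanning the covariate hull with ages at the central 90% of the fertility
age distribution — relative error in the far tails of a narrow rate curve
is not a demographically meaningful quantity); KS size on twenty
populations of $6 \times 10^4$; and bootstrap coverage at $2 \times 10^4$
woman-years with 100 replicates and data-scaled bins. Unit tests run at a
few thousand rows with coarse bins.

## Known limitations

* Treating a normalised density as a probability couples the curve's peak
  height and width; populations whose empirical schedules are both high
  and broad will be compromised between the two.
* The single-mode Gamma cannot express a secondary (premarital) fertility
  peak; a two-peak age law would be needed.
* At the default binning, weak covariate trends sit near the edge of
  statistical detectability, and the GP will correctly shrink them toward
  flatness; absence of fitted SES structure is not evidence of absence.
* The KS marginal construction and the Bonferroni count (number of
  candidate configurations) are pragmatic interpretations, both exposed in
  configuration.
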