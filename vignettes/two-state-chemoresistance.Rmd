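---
title: "Modelling chemoresistance dynamics with nested sigmoidal population models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemoresistance dynamics with nested sigmoidal population models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmix)
```

## The scientific problem

When a cancer cell population is pulse-treated with a cytotoxic drug and then
allowed to recover, its drug sensitivity can change over the following weeks
even though no single molecular marker identifies which cells are resistant.
Weekly dose-response assays — viability measured across a panel of drug
concentrations — are then the observable. `drmix` asks a model-selection
question of such data: is the population one homogeneous state whose
tolerance is fixed (single static), one state whose tolerance drifts in time
(single dynamic), or a mixture of two fixed states — sensitive and resistant
— whose *proportions* change in time (two-population)?

## The three structural models

All three build on the decreasing logistic viability curve

$$V(d) = \frac{V_{\max}}{1 + \exp\{m\,(d - c)\}},$$

where $d$ is dose (µM), $c$ is the LD50 (dose at which viability is half of
maximum, µM), $m$ is the slope (1/µM; its reciprocal $\sigma = 1/m$ is the
spread of the underlying lethal-dose distribution), and $V_{\max}$ is the
drug-free baseline viability that normalises for drug-independent death.

* **Single static** — one $(c, m)$ pooled over all assay groups; 2 free
  parameters. The null model of no time dependence.
* **Single dynamic** — an independent $(c_g, m_g)$ per group; $2G$ free
  parameters for $G$ groups. Equivalent to fitting each week separately.
* **Two-population** — a weighted sum of a sensitive and a resistant
  sigmoid whose $(c_{sens}, m_{sens}, c_{res}, m_{res})$ are shared by all
  groups, with a per-group sensitive fraction $f_g \in [0,1]$:

$$V(d, g) = V_{\max}\left[\frac{f_g}{1 + e^{m_{sens}(d - c_{sens})}} +
\frac{1 - f_g}{1 + e^{m_{res}(d - c_{res})}}\right],$$

  giving $4 + G$ free parameters fitted in a *single joint* least-squares
  problem across all groups.

$V_{\max}$ is a fixed normalisation, not a fitted parameter, so it appears
in none of the parameter counts. By default it is estimated as the mean
viability of the dose-0 records (`estimate_vmax()`). One subtlety of this
convention: the logistic at $d = 0$ equals $V_{\max}/(1 + e^{-mc})$, which
is slightly below $V_{\max}$ when $mc$ is not large, so the dose-0 mean is a
slightly conservative estimate of a generative $V_{\max}$. Every fit
function therefore also accepts an explicit `v_max` for situations — such
as simulation studies — where the baseline is known.

The assumptions worth keeping in mind: viability errors are additive,
roughly Gaussian and independent across wells; the two states' dose-response
curves are constant across groups (only the mixing fraction moves); and two
states suffice — with a 12-dose panel there is little power to resolve more.

## Fitting

Each model is calibrated by bounded nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nls.lm`) with cost tolerance `1e-10`
and parameter tolerance `1e-8` — the problems are small, so tight tolerances
are cheap. Bounds are $c \in (0, 2 d_{\max}]$, $m \in (0, 10]$,
$f_g \in [0, 1]$; fractions are bounded, never clipped after the fact.

Two choices matter for the joint mixture fit:

* **Canonical state ordering.** The mixture is symmetric under relabelling
  of the two states. We remove the label-switching degeneracy by
  reparameterising $c_{res} = c_{sens} + \delta$ with $\delta > 0$, so the
  "sensitive" state is by construction the lower-LD50 state.
* **Multi-start initialisation.** A heuristic start (LD50 at the dose whose
  pooled mean viability is nearest $V_{\max}/2$; slope $4/d_{\max}$;
  fractions 0.5) plus Latin-hypercube draws over the bounds (10 starts by
  default, slopes drawn log-uniformly); the best final residual sum of
  squares wins. The Latin-hypercube draws use an internal fixed seed and
  restore the caller's RNG state, so a fit is a deterministic function of
  its data — reshuffling records or relabelling groups does not change the
  optimum beyond optimizer tolerance.

Degenerate inputs are reported, not silently fitted: data with no dose
effect at all return `converged = FALSE`, and a recovered state separation
$\delta$ below 2% of the dose range raises an unidentifiable-mixture
warning (with no resistant signal in any group, the fraction and the
resistant state's parameters are jointly unidentifiable — only the curve
itself is determined).

## Model selection and uncertainty

Models are compared with the Gaussian least-squares AIC,
$n \ln(\mathrm{rss}/n) + 2k$, alongside the mean squared error
$\mathrm{rss}/n$; the converged model with the lowest AIC wins
(`compare_models()`). An AICc variant is available behind a flag; because
the absolute AIC scale depends on the likelihood convention, only orderings
are meaningful across software.

Confidence intervals come from case resampling with replacement
(`bootstrap_ci()`, 500 resamples by default, percentile intervals; refits
start from the original solution). The resampling is stratified **by assay
group**, which keeps every group's record count intact while letting doses
be resampled freely within it. We deliberately did not stratify at the
(group, dose)-cell level: resampling within a cell of $r$ replicates
understates the bootstrap variance by the factor $(r-1)/r$ — a 25% deficit
at the 4-replicates-per-dose design — which makes nominal 95% intervals
undercover. Group-level strata preserve the per-group parameter structure
with a negligible deficit; the test suite verifies the resulting coverage by
a 200-repetition simulate-and-refit experiment. Cell-level and unstratified
resampling remain available via the `stratify` argument.

## Synthetic assays

Because the analysis is designed for data that are not publicly deposited,
the generator (`simulate_assay()` with `make_time_course_design()` /
`make_mixture_design()`) is a first-class module. It emulates the assay
structure: the 12-dose doxorubicin panel (0–144 µM), grouped either as 8
weekly assays or as 5 reference mixtures of a sensitive and a resistant
line (resistant fractions 0, 0.25, 0.5, 0.75, 1, i.e. mixing ratios 1:0,
3:1, 1:1, 1:3, 0:1), with 4 replicates per dose by default (the replicate
count of the original assays is not published; 4 is a typical 12-well-plate
scale and is configurable). Noise is zero-mean Gaussian, truncated to
$[0,1]$, with a standard deviation that may vary with dose — either a
constant (default 0.05, a typical viability-assay replicate spread) or a
profile estimated from data by `estimate_noise_from_data()` (pooled
within-cell variance per dose). Default generative parameters in tests use
the package's reference operating point: sensitive LD50 22.4 µM (slope
0.06), resistant LD50 79.7 µM (slope 0.028), baseline viability 0.9.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about real assays: plate/edge effects and other
correlated errors, counting error that scales with cell number, cell–cell
interactions that change effective resistance in mixtures, and any
mechanistic birth/death/transition kinetics behind the weekly fractions.

All randomness flows from one root seed; each (group, dose) cell draws from
a stream derived deterministically from it, so a dataset is reproducible
and independent of iteration order.

## From fractions to cell numbers

Weekly counts give per-capita growth rates
$r = \ln(N_{t+1}/N_t)/\Delta t$ (births minus deaths per cell per day),
summarised across replicates with t-intervals (`growth_rate_series()`).
Totals are projected exponentially week over week (`project_totals()`), and
combined with the fitted resistant fractions into
$N_{res} = f_{res} N_{total}$ and $N_{sens} = (1 - f_{res}) N_{total}$,
which sum to the total exactly (`subpopulation_counts()`). This step is
purely empirical — no growth-rate difference or state-transition mechanism
is assumed. The compounded 95% interval on $N_{res}$ multiplies the
fraction interval by the total-count interval (interval arithmetic, a
deliberately conservative convention whose relative width is the product of
the inputs' relative widths); a Monte-Carlo propagation alternative
(truncated-normal fraction × log-normal total) is available via
`method = "mc"`. Both are conventions, not reconstructions of any
particular published error bar.

## Validation and identifiability

`fit_mixture_fractions()` regroups the joint fit by mixture composition and
compares estimated to measured resistant fractions; agreement is summarised
by the coefficient of determination about the line of unity,
$R^2 = 1 - \sum(\hat f - f)^2 / \sum(f - \bar f)^2$ (the measurement is
treated as truth; a regression-based $R^2$ is available since conventions
differ across reports). `run_identifiability_study()` repeats
simulate-and-refit (default 100 datasets of 5 mixtures) and reports each
parameter's estimate distribution, its 95% band and whether the generative
truth falls inside; `pairwise_fraction_tests()` then asks which mixture
compositions are statistically resolvable via Welch t-tests (unequal
variances, the robust default; no multiplicity correction by default, since
the raw pairwise tests are the quantity of interest — Bonferroni is an
option). Separability degrades continuously as the two LD50s approach each
other, which the test suite demonstrates by shrinking
$c_{res} - c_{sens}$.

## Problem sizes and runtime choices

The test suite and the acceptance script run full-size assays (8 groups ×
12 doses × 4 replicates = 384 records) for single fits, 25 independent
assays for parameter-recovery averages, 100 assays for model-selection
frequencies, and 200 simulate-and-refit repetitions (500 bootstrap
resamples each) for interval-coverage checks; bulk simulation loops use 4
multi-starts (the heuristic start is reliable on well-behaved synthetic
data) while single showcase fits use the default 10. These sizes keep the
whole suite at a few minutes on one core while leaving the Monte-Carlo
error of each checked frequency well below its acceptance margin.

## Known limitations

* Exactly two states; more states need a richer dose panel than 12 doses.
* Unweighted least squares: heteroscedastic noise is emulated by the
  generator but not exploited by the estimator.
* Percentile bootstrap (not BCa); intervals for fractions estimated at the
  [0, 1] boundary are one-sided by nature.
* The identifiability study's truth-coverage uses bands across simulations,
  not per-dataset intervals; the two agree only when bias is negligible.

## A worked example

```{r example, eval = FALSE}
tp <- two_pop_params(c_sens = 22.4, m_sens = 0.06,
                     c_res = 79.7, m_res = 0.028,
                     f_sens = 1, v_max = 0.9)
design <- make_time_course_design(seq(0.9, 0.4, length.out = 8), tp)
assay <- simulate_assay(design, noise_model(sd = 0.05, seed = 1))

cmp <- compare_models(assay, v_max = 0.9)
cmp$winner               # "two_population"
ci <- bootstrap_ci(assay, cmp$winner, v_max = 0.9, n_boot = 500)
head(ci)
```
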