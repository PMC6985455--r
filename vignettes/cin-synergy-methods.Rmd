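---
title: "Quantifying growth inhibition and drug-genotype synergy from confluency screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth inhibition and drug-genotype synergy from confluency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinsynergy)
```

## The problem

Chromosomal instability (CIN) and aneuploidy are near-universal in tumours
but rare in healthy tissue, which makes them attractive selective targets.
A practical way to look for compounds that preferentially kill CIN or
aneuploid cells is a plate-based proliferation screen: a wild-type line and
a perturbed line (a stable trisomic derivative, or a doxycycline-inducible
Mad2 knockdown that switches on a CIN phenotype) are grown side by side
under a drug panel while an imaging system records well confluency over
time. `cinsynergy` implements the quantitative core of such screens: growth
summaries per well, per-cell-line normalization, differential-sensitivity
testing, and Bliss-independence synergy scoring, together with the
cell-level statistics (phenotype counts, cell speeds, microtubule assembly
rates, mitotic timing) that usually accompany the follow-up biology.

Everything is exercised against a built-in generator that simulates screens
with known growth, drug, genotype, and interaction parameters, so each stage
has a ground truth to recover.

## Growth model and per-well metrics

Wells follow logistic growth toward a carrying capacity $K$ (100%
confluency):

$$C(t) = \frac{K}{1 + \frac{K - c_0}{c_0} e^{-r_{\mathrm{eff}} t}},$$

with the effective rate composed multiplicatively:
$r_{\mathrm{eff}} = r_{\mathrm{base}} \cdot g \cdot d \cdot (1 - \beta)$,
where $g$ is the genotype penalty (default 0.75 for the Mad2-knockdown line,
i.e. a ~25% proliferation penalty; 0.9 for the trisomic line), $d \in [0,1]$
the per-drug effect, and $\beta$ the interaction term applied only in
combination wells. A passage event divides the logistic state by the split
ratio (default 1:8 on day 4) and growth continues from the diluted state.
Measurement noise is multiplicative lognormal with unit mean; its
coefficient of variation defaults to 0.05 — imaging-based confluency
estimates do not come with a published error model, so this is a package
choice, surfaced as `noise_cv` and worth adjusting to your own instrument.

Two AUC conventions are provided. The default is the plain **sum of
confluency values over time points**, which is the screen's historical
definition and is valid whenever all compared wells share one sampling grid
(the package enforces this). The **trapezoid rule** (percent·hours) is
available for unequal grids; on 2-hourly samples of a logistic curve it
agrees with adaptive quadrature of the closed form to well under 0.5%.

The **exponential-phase cutoff** is detected by fitting least-squares lines
to (time, ln confluency) over expanding windows from the first positive
observation and returning the largest endpoint whose window keeps
$R^2 \ge$ `r2_min` (default 0.99, minimum 4 points). The underlying screen
scripts only ever stated that a cutoff "for logarithmic growth" was found,
so this concrete rule is our design; it is deterministic, matches exhaustive
window search by construction, and both parameters are exposed. If no window
qualifies the result is flagged `low_quality`. The cutoff is detected on the
**mean vehicle curve per cell line**, so drug and control wells share a
cutoff time; the relative slope then reduces to the confluency ratio at the
cutoff, because the shared time cancels.

The **manual slope** convention for daily-imaging curves,
$-\ln(C(t^\*)/100) / t^\*_{\mathrm{days}}$, is implemented literally. Note
that it *decreases* as confluency rises, which is counter-intuitive for a
growth slope; we do not second-guess the convention, we document it, and in
practice only its control-relative ratio is used. Natural log is used
throughout and confluency is converted from percent to a fraction before any
log; the choice of base cancels in relative quantities only partially, so it
is fixed rather than configurable-by-accident.

**Control normalization** divides each AUC by the mean vehicle-control AUC of
the same cell line, which removes baseline growth differences between lines
(the knockdown's ~25% penalty) before drugs are compared. Control wells
normalize to mean exactly 1.

Passage discontinuities are handled by analyzing **time windows**
separately (e.g. days 0–4 and days 4–8) rather than stitching a cumulative
curve. When a window boundary coincides with a sampled point, the default
(`boundary = "shared"`) assigns the boundary sample to both adjacent
windows: this is what makes trapezoid AUCs additive across windows and
mirrors integrating day 1–4 as $[0, 96]$ h. A strict half-open partition is
available with `boundary = "left"`.

## Differential sensitivity

For each drug the control-relative metric is compared between lines as a
log2 ratio of group means, with a two-sample t test and Bonferroni
correction over the drug family ($p_{\mathrm{adj}} = \min(1, m p)$). Two
design points deserve explanation:

* **Replicate unit.** The biological replicate is the default unit:
  technical replicates are averaged within each biological replicate, and
  each biological replicate's drug AUC is divided by the *same replicate's*
  control mean. Screens carry at least one vehicle control per plate, so
  this plate-wise normalization is both the realistic layout and the one
  that keeps replicate values statistically independent — dividing all
  wells of a line by one shared noisy control mean would introduce a common
  factor whose variance the within-group spread cannot see, inflating the
  type-I error by roughly $\sqrt{2}$. Treating all nine wells as independent
  remains available (`replicate_unit = "well"`).
* **Pooled vs unequal-variance t.** With three biological replicates per
  group, Welch's Satterthwaite degrees of freedom are so unstable that the
  test becomes noticeably conservative (measured size ≈ 0.034–0.041 at
  nominal 0.05 on null screens). Student's pooled-variance test, reasonable
  under a shared measurement protocol, measures ≈ 0.05 and is the default;
  `var_equal = FALSE` selects Welch.

Calibration is not assumed but measured: `simulate_null_pvalues()` replays
thousands of null screens through the same test functions, and
`estimate_fwer()` measures the family-wise error of the Bonferroni rule on
simulated 95-drug all-null screens (800 simulations by default in the
acceptance run; standard error ≈ 0.007).

## Bliss synergy

Fractional growth inhibition is $F = 1 - \mathrm{AUC}_{\mathrm{treated}} /
\mathrm{AUC}_{\mathrm{reference}}$, with the wild-type vehicle condition as
the reference for all four groups. Under Bliss independence the expected
combined inhibition of a drug (inhibition $F_a$) and a genotype/second
perturbation ($F_b$) is

$$E = F_a + F_b - F_a F_b,$$

and the **excess** $= F_{ab} - E$ measures synergy ($> 0$) or antagonism.
Both the absolute excess (percentage points of inhibition) and the relative
excess $(F_{ab} - E)/E$ — the "X% stronger than additive" reading — are
always reported, because published summaries use both scales
interchangeably. Negative single-agent inhibitions are clipped to zero only
inside the headline Bliss formula, never in reports.

**Significance.** The default test pairs each replicate's four wells
(reference, drug alone, perturbation alone, combination, same replicate
index): replicate $i$ contributes
$e_i = F_{ab,i} - (F_{a,i} + F_{b,i} - F_{a,i} F_{b,i})$, computed against
reference well $i$ with the *unclipped* formula, and a one-sample t test
asks whether the $e_i$ center on zero. Two details matter and were chosen
after measuring the alternatives on null simulations. First, clipping the
per-replicate inhibitions at zero before the formula biases $e_i$ downward
under the null (half of the null $F_{a,i}$ are negative), which wrecks the
test. Second, testing the per-well observed inhibitions against a *fixed*
expectation built from mean $F_a, F_b$ ignores the expectation's own
sampling error and is anti-conservative (measured size ≈ 0.08 even
unclipped). The quartet-paired excesses are independent across replicates
and the test holds its nominal 5% size (measured 0.044–0.056). The
fixed-expectation convention remains available as
`replicate_mode = "mean_expected"`, and a paired bootstrap
(`method = "bootstrap"`) resamples wells of all four groups instead. Point
estimates ($F_a$, $F_b$, expected, observed, excess) are identical across
modes.

Windowed synergy (days 0–4 vs 4–8) recomputes metrics and reference AUCs
within each window.

**A subtlety of the generator.** The interaction is injected on the growth
*rate* — mechanistically natural — while synergy is read out on AUC-derived
inhibitions, as the screens define it. These two notions of additivity do
not coincide exactly: drugs that are purely rate-multiplicative (zero
interaction) leave a small systematic AUC-scale Bliss residual whose sign
and size depend on where the curves sit on the logistic (≈ +0.004 under the
default 8-day, day-4-passage conditions; up to ≈ ±0.03–0.04 for strong
single-agent effects or mid-exponential windows). The generator therefore
reports ground truth on the AUC scale, computed from the noiseless curves
with the same AUC convention the metrics use, and recovery is always judged
against that truth rather than against an assumed zero. With nine
combination wells the paired t test is sensitive enough to flag even these
small residuals; interpreting screen output should lean on the size of the
excess, not only its p-value.

`calibrate_excess_rate()` inverts the rate→excess relation numerically
(monotone in the rate, solved by `uniroot`), so simulations can be
parameterized directly by the true AUC-scale excess on either the absolute
or the relative scale. Not every excess is reachable: the observed
inhibition cannot exceed 1, so the absolute excess is capped at
$1 - E$ — with strong single agents ($E \approx 0.7$) an absolute excess of
0.3 is impossible, which is why the recovery analyses use moderate
single-agent effects.

## Cell-level statistics

* Phenotype counts (normal / misaligned / lagging / micronucleated, etc.)
  are compared with Pearson's chi-squared test without continuity
  correction by default; the tables involved are moderate-n 2×k, where
  Yates' correction mostly over-corrects (it is available via `correct =
  TRUE`). Expected counts below 5 trigger a warning. Note the usual
  caveat, which we test rather than state: scaling all counts at fixed
  unequal proportions leaves proportions unchanged but sharpens p.
* Aneuploid-cell fractions are reported as percentages with Wilson score
  intervals (e.g. 76 of 169 knockdown cells → 45%, 95% CI 37.7–52.5%).
* Track speeds are compared with the Wilcoxon–Mann–Whitney rank-sum test:
  exact enumeration when the combined sample is ≤ 12 without ties, the
  normal approximation with tie and continuity correction otherwise. At the
  crossover the two versions agree to ≈ 0.01 (measured worst case 0.011,
  which is why the agreement property is asserted at 0.015). Tracks are
  pooled across movies by default, as screen practice does; pooling ignores
  movie-level clustering, so a stratified analysis is advisable when
  movie effects are suspected.
* Microtubule plus-end assembly rates use the **cell as the unit of
  analysis**: each cell contributes the mean of its (default 20) per-MT
  rates, and conditions are compared with an unpaired two-sided t test on
  per-cell means. Testing individual MTs would pseudo-replicate.
* Mitotic timing takes per-cell ordered timestamps (condensation start,
  last point before anaphase, full decondensation), yielding
  prophase→metaphase and anaphase→decondensation durations; groups are
  compared by rank-sum by default (mitotic-duration distributions are
  right-skewed), with a t test available.

## What the generator does and does not emulate

It emulates: logistic growth to 100% confluency, genotype proliferation
penalties, multiplicative drug effects, an injectable combination-only
interaction, the 1:8 day-4 passage, 2-h or 24-h sampling, the 3×3 replicate
structure with technical replicates sharing a biological replicate's latent
rate, and multiplicative measurement noise. It does not emulate: spatial
effects within wells, edge effects and plate gradients, drug-media
refreshment dynamics, density-dependent drug potency, cell death as distinct
from growth arrest, or segmentation artifacts. Passing recovery tests on
synthetic screens therefore demonstrates that the *computational pipeline*
is faithful and calibrated under the stated noise model, not that any
particular laboratory screen meets those assumptions.

Problem sizes used in the shipped analyses were chosen to keep the full
workflow comfortably reproducible on a laptop: 20-drug screens at 2-h
cadence over 8 days (36,666 rows each), 2,000 null simulations per
calibration, 800 simulated 95-drug screens for the family-wise error, and
50 screens of 10×10 replicates for the null-bias estimate.

## Numerical choices and degenerate inputs

* Lognormal noise uses $\sigma_{\log} = \sqrt{\log(1 + \mathrm{cv}^2)}$ with
  $\mu_{\log} = -\sigma_{\log}^2/2$, so the multiplier has mean exactly 1
  and CV exactly `noise_cv`; draws are clipped to $[0, K]$ afterwards.
* Expanding-window $R^2$ is computed from cumulative sums, clamped to
  $[0, 1]$ and rounded to 12 digits so noiseless exponentials survive
  floating point at `r2_min = 1`; a constant log-series defines $R^2 = 1$.
* Cutoff times falling between samples match the nearest sampled time, ties
  toward the earlier point.
* Zero-variance groups: two-sample comparisons return p = 1 (equal means,
  flagged degenerate) or p = 0 (unequal); the synergy test behaves
  analogously; all-tied rank-sum samples return p = 1 flagged.
* All randomness flows from explicit integer seeds (`withr::with_seed`);
  re-running any stage with the same inputs produces byte-identical output
  files, each carrying a header naming the producing stage and a hash of
  the configuration.

## Known limitations

* The Bliss machinery assumes a shared reference (wild-type + vehicle) for
  all four groups and a common AUC grid/window; designs where the
  perturbation-alone condition lives on a different plate need the
  plate-wise normalization path instead.
* AUC-scale Bliss additivity is not the same null as rate-scale
  independence (see above); with many replicates the test will flag the
  structural residual of a purely rate-multiplicative drug.
* The sum-AUC convention weights early and late time points equally, so the
  passage discontinuity makes full-run AUCs dominated by the pre-passage
  plateau unless windows are used.
* No dose–response modelling: doses are labels, one concentration per drug,
  as in the screens this package mirrors. Hill/IC50 fitting, Loewe, HSA and
  response-surface synergy models are out of scope by design.
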