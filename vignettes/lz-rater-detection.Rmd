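---
title: "Detecting biased OSCE raters with the lz person-fit statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biased OSCE raters with the lz person-fit statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterfit)
```

## The problem

In an Objective Structured Clinical Examination (OSCE), examinees rotate
through stations where a rater scores their performance on a binary
checklist. In the common in-house design each rater stays at one station all
day ("raters nested in stations"), so rater severity and station difficulty
are confounded by construction: a station with low scores may be hard, or
its rater may be stringent. Facet-type models that disentangle the two need
multiple raters per station, which in-house examinations rarely have.

Person-fit statistics offer a different route. If the checklist items'
psychometric properties are *known* from prior administrations (banked
stations), then a rater's entire vector of scores has a well-defined
probability under an item response model, and a rater whose scoring is
systematically too harsh or too generous produces a vector that is
improbable under that model — regardless of whether any other rater saw the
same examinees.

`raterfit` implements this idea end to end for a 12-station, 48-examinee,
10-items-per-station OSCE, together with the Monte Carlo machinery to
measure how often it actually works.

## The measurement model

Scores follow a two-parameter logistic (2PL) model. Examinee $j$ with latent
ability $\theta_j$ passes item $i$ with probability

$$P_i(\theta_j) = \frac{1}{1 + e^{-D a_i (\theta_j - b_i)}},$$

where $a_i$ is the item's discrimination (slope), $b_i$ its difficulty
(location), and $D = 1.702$ the scaling constant that aligns the logistic
with the normal ogive. Probabilities are clipped into
$[10^{-6}, 1-10^{-6}]$ so every downstream logarithm is finite.

### From classical statistics to 2PL parameters

Item banks from real examinations usually record classical test theory
(CTT) statistics: the proportion-correct $p$ and the point-biserial
item-total correlation $r$. `ctt_to_2pl()` converts them with the classical
normal-ogive relations

$$a = \frac{r}{\sqrt{1-r^2}}, \qquad b = \frac{\Phi^{-1}(1-p)}{r}.$$

Under the normal-ogive model this conversion exactly preserves the marginal
proportion-correct over $\theta \sim N(0,1)$ (the identity
$E_\theta[\Phi(a(\theta-b))] = \Phi(-ab/\sqrt{1+a^2}) = p$ holds for any
sign of $r$), and with $D = 1.702$ the logistic version preserves it to
well under 0.01; the test suite verifies the round trip by Monte Carlo for
every unclipped bank item.

Two guards keep the conversion total on real tables: $|r|$ is floored at
0.05 (sign preserved) so near-zero discriminations cannot produce unbounded
locations, and $|b|$ is clipped at 5. Negative discriminations are kept
negative — the packaged bank contains several, and flipping or dropping
them would quietly change the data-generating model.

### The packaged item bank

`osce_item_bank()` ships the checklist property table of a previously
administered 12-station undergraduate OSCE (120 station-item pairs). The
table's two per-item rows are labelled ambiguously, and the package
resolves the ambiguity by value ranges: one row family contains negative
entries, impossible for a proportion-correct but routine for point-biserial
discriminations of weak items, while the other lies in $(0,1)$ with mostly
high values, exactly what easy clinical stations produce. The default
`ctt_swapped` reading therefore takes the high-valued rows as $p$ and the
signed rows as $r$. Two alternative readings remain selectable:
`ctt_literal` (labels at face value; fails validation on this bank, on
purpose) and `direct_2pl` (rows already are $a$ and $b$; no conversion).

Because the stations are easy (median $p \approx 0.7$), simulated score
totals are negatively skewed — the signature of real health-professions
assessment data, and the property that later makes stringent raters easier
to catch than lenient ones.

## The lz statistic, per rater

For a binary vector $u$ with model probabilities $P$, the log-likelihood
and its model-implied moments are

$$l_0 = \sum_i \left[ u_i \ln P_i + (1-u_i)\ln(1-P_i)\right], \quad
E[l_0] = \sum_i \left[ P_i \ln P_i + (1-P_i)\ln(1-P_i)\right],$$

$$\mathrm{Var}[l_0] = \sum_i P_i(1-P_i)\left[\ln \frac{P_i}{1-P_i}\right]^2,
\qquad l_z = \frac{l_0 - E[l_0]}{\sqrt{\mathrm{Var}[l_0]}}.$$

The tests verify $E[l_0]$ and $\mathrm{Var}[l_0]$ against exhaustive
enumeration of all $2^n$ patterns on short vectors. One $l_z$ is computed
per *rater*, over the rater's full assessment vector: the station's 10
items crossed with all 48 examinees, 480 entries. Under the model $l_z$ is
asymptotically standard normal, and at 480 entries the asymptotics are
good: the null simulation in the test suite finds mean within 0.1 of 0 and
SD within 0.15 of 1.

**Flagging convention.** Misfit makes the observed likelihood *smaller*
than expected, so biased raters fall in the lower tail: the default flags
$l_z < \Phi^{-1}(\alpha)$, i.e. $-1.645$ at $\alpha=0.05$ and $-2.326$ at
$0.01$. This is the only convention that simultaneously yields
false-positive rates near $\alpha$ for conforming raters and high detection
of manipulated ones; upper and two-sided variants are available for
comparison.

## Simulating biased raters

`generate_cohort()` draws $\theta_j \sim N(0,1)$ and fills the
48 × 120 score matrix with independent Bernoulli draws.
`inject_bias()` then makes `n_biased` randomly chosen raters biased:
within each chosen rater's 480-entry vector it selects exactly
`round(rate * 480)` entry positions without replacement and overwrites
them with 0 (stringent) or 1 (lenient). Selection is at the level of
individual checklist entries, so positions that already hold the target
value are "wasted": the *empirical* bias rate is at most the nominal rate,
and for lenient bias on these easy stations it is far below it — most
entries are already 1. That asymmetry, a direct consequence of the skewed
score distribution, is why leniency is intrinsically harder to detect here.

## Which abilities enter the probability grid?

The $l_z$ probabilities require an ability for every examinee, and the
package supports three sources (`theta_mode`):

* `"mle_pre"` (default): maximum-likelihood estimates computed from the
  cohort's scores *before* any rater is manipulated. This represents an
  ability benchmark uncontaminated by the bias under investigation — in
  practice, an estimate anchored by banked parameters and the bulk of
  well-behaved stations.
* `"mle_post"`: estimates from the manipulated scores an administrator
  would literally observe. Bias then leaks into every examinee's estimate,
  and the misfit it induces spreads to *unbiased* raters: in our
  measurements pooled false-positive rates triple (≈0.11 at the 0.05
  cut-off). We keep this mode available because it quantifies an honest
  operational caveat, but it cannot be the reference configuration for a
  calibrated detector.
* `"true"`: the simulation's generating abilities; an upper bound on power.

The default was chosen because it is the only maximum-likelihood
configuration whose false-positive rates sit at the nominal $\alpha$, which
is the property that makes a flag actionable. Under it, detection rates are
essentially indistinguishable from the `"true"` upper bound.

The MLE itself exploits the concavity of the 2PL log-likelihood in
$\theta$ (for any mix of slope signs): a damped Newton iteration from 0,
clipped to $[-4, 4]$, with all-pass/all-fail patterns landing on the bound
rather than erroring — $l_z$ must remain computable for every examinee.
A 4001-point grid search backs the estimator in the tests.

## The factorial power study

`run_study()` crosses bias type (stringent, lenient) × number of biased
raters (1–6 of 12) × nominal bias rate (10–60%): 72 settings. Each
replication generates a fresh cohort, estimates abilities, injects that
setting's bias, computes 12 $l_z$ values, and records the detection rate
(flagged among truly biased) and false-positive rate (flagged among
unbiased) at $\alpha = 0.05$ and $0.01$. Seeding is hierarchical: a root
seed plus setting and replication indices determine every replication's
seed, so any single replication is reproducible in isolation.

`factorial_anova()` fits the balanced three-way fixed-effects decomposition
(through `stats::aov`) to the per-replication detection rates at
$\alpha = 0.05$ and reports partial eta squared
$SS_\text{effect}/(SS_\text{effect}+SS_\text{residual})$ per effect, with
Cohen's 0.01 / 0.06 / 0.14 thresholds labelling sizes. With tens of
thousands of replications, $F$ and $p$ are dominated by sample size;
$\eta_p^2$ is the quantity worth reading. A hand-computed cell-means
decomposition on a small grid serves as the numerical oracle in the tests.

### Problem sizes

The packaged analyses (test suite and `scripts/acceptance.R`) run the full
grid at 100 replications per setting — 7,200 replications, about a minute
vectorized — which puts roughly a ±0.03–0.05 Monte Carlo standard error on
per-setting detection means. Calibration checks pool ≥5,000 null raters.
`reps` scales freely for tighter error bars.

### What the simulation does and does not emulate

The generator reproduces the structural features that drive the science:
negatively skewed easy-station data, raters nested in stations, known
(banked) item parameters, and entry-level bias injection with its
sub-nominal empirical rates. It does **not** emulate: item-parameter
estimation error (parameters are treated as known; with estimated
parameters detection would degrade), mixed bias types within one
administration, other rater effects (halo, central tendency, contrast),
polytomous or global-rating scales, or examinee-side aberrance. Passing
tests therefore certify the statistic's behaviour under the stated
conditions, not its field performance on real, messier data. A flagged
$l_z$ also cannot say *why* a rater misfits — direction must come from the
rater's mean score level.

## Numerical choices, in one place

| Constant | Value | Role |
|---|---|---|
| $D$ | 1.702 | logistic/normal-ogive scaling; configurable to 1 |
| $\varepsilon$ | $10^{-6}$ | probability clipping inside `prob_correct()` |
| $|b|_{\max}$ | 5 | difficulty clipping in `ctt_to_2pl()` |
| $|r|_{\min}$ | 0.05 | point-biserial floor before conversion |
| $\theta$ bound | $\pm 4$ | MLE search interval and boundary value |
| var floor | $10^{-12}$ | degenerate-variance guard in `lz_statistic()` |
| cut-offs | $\Phi^{-1}(\alpha)$ | lower-tail flagging at 0.05 / 0.01 |

Ties and degenerate inputs: a flat item ($a = 0$) contributes probability
0.5 everywhere and zero variance to $l_z$ — an all-flat station raises the
degenerate-variance error rather than returning an arbitrary number;
constant ANOVA responses report $\eta_p^2 = 0$; unbalanced ANOVA input is
refused rather than reweighted.

## Known limitations

* Findings are conditional on the packaged bank's skew; a bank of hard
  stations would flip the stringent/lenient asymmetry.
* The lower-tail normal cut-off is slightly conservative with estimated
  abilities (false positives ≈0.044 at nominal 0.05); corrections of the
  Snijders type are out of scope.
* The `mle_post` mode shows that naive application to contaminated ability
  estimates inflates false alarms; real deployments need an uncontaminated
  ability anchor.
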