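---
title: "The Nova-Conhecimento knowledge score: model, simulation and validity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Nova-Conhecimento knowledge score: model, simulation and validity analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novascore)
library(dplyr)
```

## The instrument and the score

Nova-Conhecimento measures whether a person can tell foods apart by their
degree of industrial processing. Twelve foods from four everyday categories
(banana, beef, corn, dairy) are each rated for healthiness on a 1–10 scale.
Within a category the three foods span the scored Nova groups: G1
(unprocessed/minimally processed, e.g. fresh banana), G3 (processed, e.g.
banana sweet) and G4 (ultra-processed, e.g. a banana-flavored cereal bar).
Culinary ingredients (G2) are not rated: they are consumed in preparations,
not on their own.

A respondent who has internalized the dietary-guideline ordering should rate
G1 above G3 above G4 within every category. Scoring counts the three strict
pairwise comparisons per category: all three correct earns 2 points, exactly
two earns 1, anything less earns 0, giving a 0–8 total.

```{r}
score_category(10, 5, 1) # G1 > G3 > G4
score_category(10, 1, 5) # G1 > G4 > G3
score_category(5, 5, 5) # ties never earn points
```

### Policy choices the rules leave open

Three edge cases are not pinned down by the verbal scoring rules; each is an
explicit `scoring_policy()` field so that analysts can state exactly what
they computed.

* **Ties.** "Tied ratings earn nothing" can mean the tied *pair* is
  incorrect or the whole *category* is voided. We default to the pairwise
  reading (`tie_policy = "pair_incorrect"`) because it is the minimal
  interpretation: (9, 9, 2) still demonstrates that both tied foods are
  recognized as healthier than the ultra-processed one, and earns 1 point.
  `"zero_category"` implements the stricter reading.
* **Single-correct-pair orderings** such as G3 > G4 > G1 sit between the
  1-point and 0-point examples. The default awards 0 — 1 point is reserved
  for exactly-two-correct configurations — with
  `one_pair_policy = "one_point"` available.
* **Missing ratings.** No imputation, ever: an unrated item makes its
  category incomplete (`NA` points). By default the total is reported only
  when all categories are complete (`missing_policy = "total_requires_all"`),
  matching a complete-responses analysis; `"partial_sum"` reports the raw
  sum over complete categories and never prorates it upward.

Ratings must be integers within the instrument scale; the validator rejects
anything else before scoring, naming the respondent and item, because silent
coercion hides data-entry errors.

## The synthetic-data generator

No respondent-level data ship with the package, so every downstream stage is
exercised on synthetic data whose structure mirrors what the analyses
assume. The generator is first-class, tested code.

### Rating model

Each respondent has a latent knowledge parameter $k \in [0, 1]$. An item in
Nova group $g$ has latent healthiness mean $m_g$ (defaults $m_{G1} = 9$,
$m_{G3} = 6$, $m_{G4} = 3$ on the rating scale) and the emitted rating is

$$r = \mathrm{clamp}\!\left(\mathrm{round}\!\left(\bar m + k (m_g - \bar m) + \varepsilon\right),\ 1,\ 10\right),
\qquad \varepsilon \sim N(0, \sigma^2),$$

with $\bar m$ the mean of the group means. At $k = 1$ with $\sigma = 0$ the
Nova ordering is reproduced exactly (total = 8); at $k = 0$ group separation
vanishes and the expected total equals the chance-level value obtained by
exhaustively averaging the category rules over i.i.d. discretized-normal
ratings — both facts are pinned down in the test suite. This is the simplest
model whose single parameter maps monotonically onto the score, which is
what parameter-recovery tests need; it does not attempt to model response
styles (end-aversion, anchoring) of real raters.

### Calibration

$k$ is Beta-distributed per group. With $\sigma = 1.5$ fixed for all
scenarios, the Beta parameters were chosen once, by grid simulation, so that
mean total scores land on the targets that characterize the populations the
instrument was validated in:

| scenario | n | k mean (sd) | target mean score | simulated mean (SD) |
|---|---|---|---|---|
| `scenario_nutrition_students()` | 76 | 0.89 (0.12) | 6.7 | 6.68 (1.08) |
| `scenario_education_students()` | 99 | 0.55 (0.10) | 5.3 | 5.34 (1.39) |
| `scenario_nutrinet_cohort()` | 1245 | 0.60 (0.10) | 5.6 | 5.59 (1.34) |

One structural limitation: at a mean near 5.3 the category-level point
process already contributes ≈1.35 SD to the total, so the generator cannot
reach the 1.2 SD reported for real comparison-group students without making
respondents internally more consistent than this model allows. Group
*means*, which drive the discriminant comparison, are matched to within 0.1;
SDs for the lower-knowledge groups run ≈0.15 high.

Covariates (sex, age, education) follow the published sample descriptions
and are drawn independently of $k$: no score–covariate confounding is
simulated because none is reported. Tests passing on these data therefore
show that the pipeline recovers the structure it assumes — not that real
populations lack confounding.

### Recall model

True usual UPF intake is linear in the score,
$u_i = \beta_0 + \beta_1 \cdot \text{score}_i + b_i$ with
$b_i \sim N(0, \sigma_b^2)$, truncated to $[0, 100]$; each of $n_i \in
\{1, 2, 3\}$ recalls (drawn with probabilities 0.105 / 0.178 / 0.716,
the completion pattern observed in the cohort, normalized from the printed
99.9% total) adds day-to-day noise $N(0, \sigma_w^2)$, truncated likewise.
Defaults: $\beta_1 = -1.03$ percentage points per score point,
$\beta_0 = 27.36$ (so the cohort mean sits at 21.6%), $\sigma_b = 9.0$ (so
the SD of usual intake is ≈9.1 after adding score-driven variance), and
$\sigma_w = 3.0$.

The within-person SD deserves a comment. Real single 24-hour recalls of UPF
share of energy vary day-to-day by considerably more than 3 percentage
points. We keep $\sigma_w$ small because the package's usual-intake
estimator (next section) omits covariate modeling: it shrinks *all*
between-person deviations — including the score-driven signal — by the
reliability factor $\lambda$. The regression of shrunken estimates on the
score is therefore attenuated by $E[\lambda]$, and at the default variance
ratio $E[\lambda] \approx 0.95$, small against the slope's sampling error at
n = 1,245. With field-typical $\sigma_w \gtrsim 10$ the attenuation would
dominate, and recovering the generating slope would require the covariate-
aware machinery of a full usual-intake method. This is a limitation of the
simplified estimator, stated here so nobody mistakes the calibrated
simulation for evidence about noisier designs.

Truncation to $[0, 100]$ (rather than resampling) introduces negligible bias
at these SDs. Seeding: each generator call derives its RNG state from the
scenario seed (ratings/covariates at the seed itself, recalls at a fixed
offset), so scenarios are reproducible end to end and rating and recall
noise never share a stream.

## Usual-intake estimation

`variance_components()` fits the one-way random-effects decomposition by
method of moments: pooled within-person variance
$\hat\sigma_w^2 = \mathrm{MSW}$, and
$\hat\sigma_b^2 = (\mathrm{MSB} - \mathrm{MSW}) / n_0$ with the classical
unbalanced-design effective replicate count
$n_0 = (N - \sum_i n_i^2 / N)/(k - 1)$. Negative between-person estimates —
expected in small samples when the true value is near zero — are truncated
to 0 with a warning, standard method-of-moments practice.

`estimate_usual()` then shrinks each person mean toward the grand mean:

$$\lambda_i = \frac{\hat\sigma_b^2}{\hat\sigma_b^2 + \hat\sigma_w^2 / n_i},
\qquad \hat u_i = \bar y + \lambda_i\,(\bar y_i - \bar y).$$

$\lambda_i \in [0, 1]$ and increases with the number of recalls; when
$\hat\sigma_w^2 = 0$ the person mean is returned unchanged (we define
$\lambda = 1$ in the degenerate all-constant case, where every candidate
estimate coincides anyway), and when $\hat\sigma_b^2 = 0$ every estimate
collapses to the grand mean. Under the calibrated scenarios the shrunken
estimates have strictly lower mean-squared error against the simulated true
usual intake than raw person means — the point of deattenuation.

This is deliberately the *shrinkage core only*. The Multiple Source Method
used with real cohort data additionally models covariates, applies a
Box-Cox-type transformation, and handles episodically consumed foods via a
consumption-probability part. UPF share of energy is near-continuous and
consumed daily, so the two-part and transformation machinery matters least
here — but no equivalence with MSM output is claimed anywhere.

## The validity battery

* `mann_whitney()` — midrank U statistic; exact p by full enumeration of
  group assignments when both groups have ≤10 observations without ties (or
  on request, where it remains valid under ties); otherwise the normal
  approximation with tie-corrected variance and no continuity correction.
  The exact path is checked against an independent enumeration oracle, the
  approximate path against `stats::wilcox.test(correct = FALSE)`, and the
  test's size against simulation (5% nominal).
* `chi_square_2x2()` — Pearson chi-square via `stats::chisq.test`, Yates
  continuity correction on by default: with the correction, the printed
  comparability p-values of the two-group study (0.064 for sex, 0.121 for
  education) are reproduced, indicating the original analysis used it. A
  flag disables it; the uncorrected statistic equals the classical
  closed-form $n(ad-bc)^2$ formula.
* `welch_t_from_summary()` — Welch t with Satterthwaite degrees of freedom
  from printed group summaries (means, SDs, sizes), reproducing the age
  comparison p = 0.920.
* `ols_adjusted()` — `stats::lm` of usual intake on a score term plus sex,
  age and education, with classical standard errors; factor covariates are
  coded as indicators against their first level (the coding is not specified
  by the original analysis; indicators against a reference are the safest
  default for a 3-level education factor). Rank deficiency and undersized
  designs (< 10 observations above the parameter count) are hard errors.
* `sample_size_two_groups()` — a documented *reconstruction* of the
  discriminant-phase planning: the normal-approximation two-sample size with
  unequal SDs, divided by 0.864, the worst-case asymptotic relative
  efficiency of the Mann-Whitney test against the t test. With delta 0.5,
  SDs 0.8 and 1.2, alpha 0.05 and power 0.80 it returns 76 per group,
  matching the published requirement; it is not claimed to be the original
  authors' exact procedure.

`discriminant_validity()` assembles the grouped descriptive table with a
Mann-Whitney p per category and total; `convergent_validity()` fits one
adjusted regression per component (each category score and the total), with
an identical covariate set across rows. All significance is two-sided at 5%.

## Problem sizes and numerical choices

The simulation-based checks in the test suite run at the study's own sizes:
the two-group comparison at n = 76/99 (500 replicate seeds for the rejection
rate), the cohort at n = 1,245 (200 replicate seeds for confidence-interval
coverage of the generating slope), type-I-error simulations at n = 25 per
arm over 1,000 seeds, and variance-component recovery at n = 200 versus
2,000 with tolerances halving. Exact Mann-Whitney enumeration is limited to
$\binom{n_1+n_2}{n_1} \le 2 \times 10^5$ assignments; beyond that the
tie-corrected normal approximation takes over. Comparisons against the
closed-form OLS oracle are at $10^{-8}$; scoring oracles are exact integer
comparisons over the full $10^3$ rating grid.

## Known limitations

* The rating model has one knowledge dimension and symmetric noise; real
  response behavior (category-specific knowledge, scale-use styles) is
  richer, so calibration SDs for low-knowledge groups run slightly high.
* The usual-intake estimator shrinks outcome-side signal (see above);
  with few recalls and large within-person noise, regression slopes on its
  output are attenuated. Use it for deattenuating descriptives and for the
  calibrated simulation designs it ships with.
* Published cohort quantities (group means 6.7/5.3, slope −1.03, mean
  intake 21.6%) derive from participant data that are not redistributable;
  here they serve as generator calibration targets, not as values the
  package claims to reproduce from raw data.
* The instrument itself ships as structured metadata (items, categories,
  groups, scale); the food photographs, ingredient lists and label images
  used in data collection are out of scope.
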