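---
title: "A continuous, probabilistic trophic state index for lakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuous, probabilistic trophic state index for lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicstate)
```

## Motivation

Trophic state summarizes where a lake sits on the nutrient-enrichment
gradient. The classical indices are single-variable, discrete and
deterministic: a chlorophyll-based index and a phosphorus-based index can
place the same lake in different classes, the hard class boundaries hide how
close a lake is to a transition, and no uncertainty accompanies the label.
`trophicstate` treats the class as an *ordered categorical response* driven
by a *continuous latent index*, so that a lake is described by (i) its
position on the trophic continuum and (ii) four class probabilities that
quantify classification uncertainty.

## The model

For lake $i$ with standardized predictors $x_i$ (log Secchi disk depth, log
total nitrogen, log total phosphorus, elevation) and slope vector $A$,

$$\mathrm{TSI}_i = x_i^\top A, \qquad
z_i \sim \mathrm{logistic}(\mathrm{TSI}_i,\, 1),$$

and the observed state is the interval of $z_i$ among ordered cutpoints
$c_1 < c_2 < c_3$:

$$y_i = k \iff c_{k-1} \le z_i < c_k,
\qquad c_0 = -\infty,\; c_4 = +\infty.$$

Equivalently, on the cumulative-logit scale,
$\operatorname{logit} \Pr(y_i > k) = \mathrm{TSI}_i - c_k$: one linear
predictor shifts all three cumulative logits equally (the proportional-odds
assumption). Class probabilities telescope,
$p_k = \Pr(y > k-1) - \Pr(y > k)$, and always sum to one.

Three identifiability conventions matter and are fixed throughout:

* **No intercept.** The cutpoints absorb location; adding a constant to the
  index and to all cutpoints changes nothing (this shift invariance is
  property-tested).
* **Unit latent scale.** With free slopes and free cutpoints a free logistic
  scale is not identifiable, so the latent noise scale is fixed at 1. The
  `latent_scale` field on `polr_params` exists as metadata only.
* **Boundary convention.** The latent intervals are half-open,
  $[c_{k-1}, c_k)$, with the top class closed below: a value exactly at a
  cutpoint is assigned upward. The underlying continuous distribution puts
  zero mass on the boundary, so this is a documented tie-break, not a
  modeling choice.

Two classifiers are exposed. `classify_interval()` applies the interval rule
to the index — this is the published rule and the one used by
`evaluate_holdout()`. `classify_map()` takes the most probable class; it can
differ from the interval rule only in a narrow band adjacent to each
cutpoint (where the modal class switches slightly away from the cutpoint
itself, because the adjacent intervals have unequal widths). A grid oracle
in the test suite measures that band at under 0.2 index units for the
national parameterization.

## Variable transformation

Secchi depth, total nitrogen and total phosphorus are natural-log
transformed — environmental concentration variables are canonically
log-normal — and elevation stays on its raw scale (it is not a
concentration, and elevations at or below sea level are legitimate). All
four predictors are then centered and scaled using means and standard
deviations (n−1 denominator) **fitted on the training set only**; prediction
on new lakes reuses the training spec. Re-fitting standardization on
evaluation data would leak information and silently change what the
coefficients mean. Rows with missing required fields are deleted with a
logged count; non-positive Secchi/TN/TP values are an error under the strict
reading policy (they have no logarithm) or dropped under the lenient one.

## Estimation

**Maximum likelihood** (`fit_polr_mle`). The cutpoint order constraint is
removed by the reparameterization
$c = (t_1,\; t_1 + e^{t_2},\; t_1 + e^{t_2} + e^{t_3})$, and the
unconstrained 7-parameter problem is solved by BFGS with an analytic
gradient, followed by Newton polishing (finite-difference Hessian of the
analytic gradient). Convergence is declared when the largest component of
the gradient of the **mean** (per-observation) log-likelihood falls below
`tol = 1e-8`; the per-observation scaling makes the criterion meaningful
across sample sizes. Starting values are zero coefficients and cutpoints at
the logits of the cumulative class frequencies — the exact fit under a
predictor-free model. Standard errors come from the inverse *observed*
information on the natural $(A, c)$ scale, the standard practice that
matches reference ordinal-regression software closely (the test suite
checks coefficients, cutpoints and standard errors against an independent
implementation). Coefficient magnitudes above 25 on the standardized scale
trigger a perfect-separation warning and `converged = FALSE`: the
likelihood is then unbounded and the estimates meaningless.

**Numerical stability.** Class probabilities are computed on the log scale.
The edge classes use the logistic log-CDF directly; the middle classes use
the log-difference-of-CDFs with the `log1mexp` split (use
$\log(-\mathrm{expm1}(d))$ for small $|d|$, $\mathrm{log1p}(-e^d)$
otherwise), which keeps the log-likelihood accurate to 1e-8 out to indices
of magnitude 30 (tested against reflected closed forms and a quadrature
oracle). An observation whose class has zero probability at working
precision contributes $-\infty$, not an exception.

**Posterior sampling** (`fit_polr_bayes`). A random-walk Metropolis sampler
in the unconstrained parameterization, with independent Cauchy(0, 2.5)
priors on the standardized coefficients — the conventional
weakly-informative choice for standardized inputs — and flat priors on the
ordered cutpoints (implemented via the log-Jacobian $t_2 + t_3$ of the
reparameterization, so every retained draw is automatically ordered). The
proposal is the MLE curvature scaled by $2.4^2/7$; chains start at jittered
MLE values. Defaults are 4 chains × 2,000 retained draws after 1,000
warm-up iterations. A split R-hat is reported per parameter; values above
1.1 raise a recorded warning rather than an error, because short exploratory
runs are legitimate. At the sample sizes used here the posterior means track
the MLE closely, which the tests assert; the sampler's value is the full
posterior (e.g., probability statements about cutpoints).

## Variable selection

Candidate predictors are ranked by random-forest permutation importance
(percent increase in out-of-bag MSE when a predictor is permuted; 5,000
trees by default), then nested forests on the top-$m$ subsets trace an
error curve, and the chosen size is the smallest $m$ beyond which no
additional variable reduces the out-of-bag error by at least the threshold
(default 0.1) — an elbow rule. Two deliberate choices:

* The 4-level ordinal response is coded 1–4 and the forest runs in
  **regression mode**, because %IncMSE-based importance has no
  classification-forest analogue. The expected "response has few unique
  values" warning is muffled inside the module; it is the design, not an
  accident.
* The selection rule is an **error-increment** rule, not an absolute-error
  target: an absolute "MSE = 0.1" criterion would be unreachable on noisy
  data and trivially satisfied on clean data, while the increment reading
  selects the same compact subsets in practice.

Tree induction is delegated to the `randomForest` package; the module's
substance is the ranking and selection logic. Nested-curve fits default to
1,000 trees (the curve needs stable OOB errors, not importance estimates,
so fewer trees than the ranking suffice).

## Evaluation

Because the three classical single-variable classifications disagree,
evaluation restricts to **consensus-classified** lakes: those whose
available reference labels (at least two of chlorophyll-*a*-, TN- and
TP-based) all agree. A 90/10 hold-out split (deterministic given a seed)
separates training from evaluation. Reported metrics are overall accuracy
(trace of the confusion matrix over its total; rows are the actual state,
columns the predicted state) and per-class one-vs-rest **balanced
accuracy**, the mean of sensitivity and specificity, which does not inflate
under class imbalance. Identities such as "overall accuracy equals the
count-weighted mean of per-class sensitivities" and invariance of balanced
accuracy under duplication of every observation are property-tested.

On the published national hold-out confusion matrix, the recomputed
oligotrophic balanced accuracy is 0.93 (two decimals), matching the reported
value; the recomputed overall accuracy is 47/73 ≈ 0.64, and the recomputed
meso/eu/hyper balanced accuracies are 0.75/0.70/0.75, which do **not** match
the reported 0.68 and 0.83/0.72/0.73 under either matrix orientation. The
package asserts the values derivable from the printed matrix and documents
the discrepancy rather than targeting the irreproducible numbers.

## The simulator: what it does and does not emulate

`simulate_lakes()` is the generative reading of the model itself: draw
predictors, compute the index, add unit logistic noise by inverse-CDF
sampling of uniform deviates (bit-reproducible across platforms for a fixed
seed), cut into classes.

* **standardized mode** draws 4 iid standard-normal predictors — the
  idealized study condition used for parameter-recovery experiments
  (20,000 lakes recovers every coefficient and cutpoint within ±0.05; Wald
  95% intervals cover each parameter 90–99% of the time over 100 replicates
  of 2,000 lakes).
* **raw mode** draws log-normal Secchi/TN/TP (default medians 2 m,
  600 µg/L, 30 µg/L, log-SD 1 — typical national-survey magnitudes) and
  normal elevation (mean 400 m, SD 500 m), then runs the package's own
  transform-standardize path before computing the index, exercising the
  full read → transform → fit pipeline.

`make_reference_labels()` emulates the three imperfect single-variable
classifiers by copying the true state and independently slipping to an
adjacent class with a configurable noise rate, which gives
`consensus_filter()` a closed-form retention rate to test against.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real surveys: correlated predictors (real nutrient
concentrations and clarity are strongly inter-correlated), spatial and
ecoregional structure, survey design weights, measurement error in Secchi
readings, and reference labels whose errors are correlated with the
predictors themselves. Simulated recovery shows the estimator is correct
under the model; it does not show the model is correct for any particular
lake population.

## Problem sizes and defaults

The package's standard experiment sizes, chosen to make Monte Carlo error
small relative to the tolerances asserted: 20,000 lakes for point-estimate
recovery (MLE standard errors ≈ 0.02 on the standardized scale), 100
replicates of 2,000 lakes for interval coverage, 100,000 draws for
class-frequency checks against quadrature (±0.01), and 10 replicate seeds
of a 350-lake, 70-candidate table (4 equally strong signals, 66 pure-noise
variables) for the selection rule, which picks exactly 4 predictors in at least
90% of seeds. The selection fixture uses equal signal strengths of 3
standardized-logit units so that each informative variable contributes an
out-of-bag error reduction comfortably above the 0.1 threshold while the 66
noise variables contribute none.

## Known limitations

* The proportional-odds assumption (one slope vector for all three
  cumulative logits) is imposed, not tested; no unequal-slopes alternative
  is provided.
* Only the logit link is implemented.
* The model is single-level: no lake-group or ecoregion random effects, and
  no spatial correlation.
* The Metropolis sampler is adequate for this 7-parameter posterior but is
  not a general-purpose MCMC engine; heavily imbalanced classes or tiny
  samples may need longer chains than the defaults.
* Standard errors are asymptotic (observed information); for small samples
  the Bayesian route gives better-calibrated uncertainty.
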