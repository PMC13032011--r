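---
title: "Unit-level causal attribution: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit-level causal attribution: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unitcausal)
```

## The problem

A feedforward classifier trained on a clinical cohort learns *some* mapping
from inputs to class probabilities, but saliency-style attributions
(gradients, SHAP, LIME) answer an associational question: how does the
output co-vary with an input? `unitcausal` answers the interventional one:
how would the output respond if an input were *set* to a value, with its
usual causes severed — Pearl's `do`-operator applied at the network's input
layer. The package is built around a pediatric-myopia use case: a 16-feature
cohort (refraction, ocular biometry, behavioural and dietary exposures,
heredity), a binary myopia outcome defined by cycloplegic refraction
CR ≤ −0.5 D, and a 16-12-8-2 ReLU/softmax classifier.

The pipeline has five stages, each a module of the package:

1. **Causal discovery** over the input features (PC algorithm with a
   degenerate-Gaussian likelihood-ratio CI test for mixed data).
2. **Unit classification**: each input is Isolated (no causal links among
   inputs), Pure (only outgoing, possibly mediated, influence) or
   Confounded (has parents among the inputs, hence backdoor paths).
3. **Attribution** with the engine matching the class: Taylor-approximated
   intervention expectations (Isolated), path-product mediation (Pure), or
   backdoor-adjusted R-learner meta-learning over discretized treatments
   (Confounded).
4. **Refutation** of any estimate with five falsification strategies.
5. A **synthetic cohort generator** with a known ground-truth structural
   causal model, so that every stage is testable against truth.

## The synthetic cohort and its ground truth

The real cohort this design emulates is not publicly deposited, so the
generator is a first-class module rather than a test fixture. Its
ground-truth SCM reproduces the structure reported for the real data: six
variables (PWG, GENDER, NAR, DAR, K1, K2) are direct causes of both axial
length (AL) and cycloplegic refraction (CR); HEIGHT and REDM affect AL
only; AL directly causes CR (15 directed edges over 10 variables); CB,
EGG, NW, PULSE, WHIM and DTO are edge-free. Children are linear in their
parents with Gaussian noise; sources are Gaussian (continuous measures) or
categorical (dietary frequencies, parental myopia, gender) with documented
probabilities. All constants live in one table
(`unitcausal:::myopia_scm_constants()`).

Design choices worth knowing:

* **Signs.** AL→CR is negative (longer eyes are more myopic) and
  HEIGHT→AL positive, the two qualitative constraints the use case pins
  down. The remaining coefficients were chosen for *faithfulness at scale*:
  with a dominant AL→CR coefficient, conditioning on CR induces an
  association between a source and AL that can nearly cancel the direct
  edge (the cancellation ratio is reached when the source's CR coefficient
  is about −1.4 times its AL coefficient at our scales), making a true
  edge statistically invisible. The default table keeps every edge's
  partial signal well away from that ratio, so the structure is
  recoverable from realistic sample sizes. This is a real property of
  linear-Gaussian systems, not a convenience: a generator that silently
  violates faithfulness cannot validate a constraint-based discovery
  stage.
* **Class balance.** The CR intercept is derived in closed form so that CR
  centres on the −0.5 D label threshold, keeping the myopic fraction near
  50% and both output classes trainable.
* **No clipping.** Ranges are kept plausible by choice of means and SDs
  rather than truncation, because clipping would break the linear-Gaussian
  form that the mediation engine and the tests rely on. Consequently a few
  extreme draws can fall outside the documented ranges; the schema records
  the plausible ranges, not hard bounds. The published K2 range (38–183)
  is physiologically implausible for corneal keratometry, so K2 uses a
  K1-like range.
* **What is not emulated.** The real data are a six-year longitudinal
  panel reduced to progression rates, cumulative exposures and multi-year
  averages; the generator emits the processed cross-sectional table
  directly. Passing tests therefore demonstrate correctness of the
  *methods* under the stated assumptions — linearity, Gaussian noise, no
  latent confounding, complete cases — not robustness to longitudinal
  preprocessing artefacts, missingness, or nonlinear physiology.

## Causal discovery for mixed data

The PC algorithm starts from the complete undirected graph and removes an
edge as soon as a conditional-independence test accepts independence given
some subset of the endpoints' neighbourhoods, then orients v-structures
(`a → c ← b` for unshielded triples whose separating set excludes `c`) and
closes under Meek's four propagation rules. Orientation conflicts are left
undirected rather than forced, and an orientation that would close a
directed cycle is refused, so the output's directed part is always
acyclic.

The CI test is a Gaussian likelihood-ratio test on a *degenerate Gaussian*
embedding: continuous columns standardized, each discrete column replaced
by one-hot indicators with a reference level dropped. Testing `x ⊥ y | C`
compares the residual covariance determinant of `y`'s block regressed on
`C`'s blocks with and without `x`'s block:
`stat = n · log(det Σ_y|C / det Σ_y|C∪x)`, referred to χ² with
(x-columns × y-columns) degrees of freedom. Two details matter:

* **Symmetry.** The determinant ratio is a canonical-correlation quantity
  and is *identical* whichever block is regressed on which, so no
  direction needs to be privileged and no multiple-testing correction
  across directions is needed. (An earlier design sketch symmetrized two
  directional tests with a Bonferroni factor; that is a no-op
  mathematically and would only shift the type-I calibration, so the
  single symmetric statistic is used.) Measured type-I error at nominal
  0.05 is 0.01–0.10 across 200 null simulations.
* **Sufficient statistics.** All tests for one data set are determinant
  computations on sub-blocks of a single embedded covariance matrix, which
  is what makes repeated discovery runs at n = 20 000 cheap.

Defaults: α = 0.05 for exploratory use (the recovery analyses use 0.01),
conditioning depth capped at 3 — appropriate for 16 variables at cohort
scale, and the reason two specific spurious adjacencies (HEIGHT–CR,
REDM–CR) can survive at very large n: their minimal separating set is all
seven other parents of CR, beyond any depth-3 search. The structural
Hamming distance budget in the recovery analyses absorbs exactly this.
Node, pair and subset enumeration is lexicographic throughout, so results
are reproducible for a given data set. The optional PCA switch
(`use_pca = TRUE`) merges groups of continuous columns with |r| > 0.95
into principal-component blocks during testing only and maps edges back
to the member variables afterwards; it is off by default because the
default cohort has no such collinearity.

## Attribution engines

**Isolated units.** The intervention expectation
`E[y | do(x_i = α)]` is approximated by a second-order Taylor expansion
around the (standardized) input mean:
`f(μ) + ½ tr(∇²f(μ) · Σ)`, where the do-operator pins `μ_i = α` and zeroes
the i-th covariance row/column (a fixed variable neither varies nor
co-varies). Curves are swept over a grid of `num = 10` evenly spaced
values between the observed 1st and 99th percentiles — Table-range
extremes would extrapolate the network far outside its training support.
For binary units the two-point grid reports the interventional contrast
`E[do(1)] − E[do(0)]`; for continuous grids the reported ACE is the grid
average of the intervention expectations (a midpoint quadrature of the
interval-averaged effect), and the plotted `centered` curve subtracts each
class's own mean, which is how trends are read. The two class curves are
exact mirror images because softmax probabilities sum to one.

The ReLU network is only piecewise smooth, and this is the engine's main
numerical caveat. Away from kinks the hidden stack is locally linear, so
the analytic Hessian is `Jᵀ D J` with `D` the softmax curvature — cheap
and exact, and cross-checked against central finite differences (step
1e−3) in the tests. At a kink the pointwise Hessian misses the delta part
of the distributional second derivative, which contributes an O(σ²) term
whenever the mean sits within a few perturbation-SDs of a kink.
`kink_margin()` measures that distance; the Monte-Carlo validation scales
the covariance so every kink is ≥ 4 SDs away (the "second-order regime"),
where the approximation agrees with a 10⁵-draw Monte-Carlo oracle within
3 MC standard errors on 20/20 random networks. Evaluation points landing
exactly on a kink are perturbed by 1e−6 with a warning.

**Pure units.** Under the linearity assumption, every directed path
contributes the product of its edge coefficients, and the total effect is
the path sum. Edge coefficients come from OLS of each node on *all* its
parents jointly (partial, not marginal, slopes). The intervention then
shifts each descendant's mean by (total effect) × (displacement), and the
covariance is replaced by its Schur complement with respect to the
intervened unit — removing exactly the variance the mediators inherited
through it, which both matches do-semantics for a parentless unit and
preserves positive semidefiniteness. The path-sum machinery is validated
against backdoor-adjusted regression on random linear SCMs (3 SE at
n = 20 000) and exactly on noise-free chains. Nonlinear mediation is out
of scope; on strongly nonlinear systems the linear path products are a
first-order summary only.

**Confounded units.** Units with parents need adjustment. The treatment
is the unit's membership in the upper of two adjacent bins (equal-width or
equal-frequency, k = 10 by default, mirroring the ten-group discretization
used in the use case), the outcome is the classifier's class probability
(continuous, for variance reduction — a flag switches to hard labels),
and the adjustment set is the unit's parents, always a valid backdoor set
in a DAG without latent confounders (and verified by the d-separation
oracle on the pruned graph). The outcome node joins the graph as a child
of CR only, because the label is a deterministic threshold of CR.

Effect estimation is an R-learner: cross-fitted propensity scores
(gradient-boosted, clipped to [0.01, 0.99]), cross-fitted per-arm outcome
models trained with inverse-propensity weights and combined as
`m(x) = e·μ₁ + (1−e)·μ₀` (the IPW per-arm stage is what makes the
procedure "domain-adaptive" in the covariate-shift sense: treated and
control distributions are reweighted toward each other), then a weighted
residual-on-residual regression for `τ(x)` minimizing
`Σ[(Y−m) − τ(X)(T−e)]²`. The effect model is a 10:1 convex combination
(10/11, 1/11) of a gradient-boosted learner and a random forest — the
combination is applied to the τ̂ predictions, one of the places where the
design was genuinely open. The `R score = 1 − L_R/L_base` compares the
fitted τ̂'s cross-validated R-loss against the best *constant* effect; the
baseline constant is the R-loss minimizer `Σwỹ/Σw`, which makes the
constant model's score exactly zero by construction (an identity the
tests assert to 1e−9). Cross-fitting uses 5 folds everywhere; all seeds
are explicit arguments.

## Refutation

Any estimator closure `function(cohort) → effect` can be falsified with
five perturbations: bootstrap resampling (BV), added random common causes
(ARCC; the added `arcc_*` columns are absorbed into the adjustment set by
the estimator factories), subset validation (DSV, fraction 0.8), placebo
treatment (permuted treatment column) and dummy outcome (outcome replaced
by noise). Relative strategies report `|new − est| / |est|` and pass below
10%; placebo/dummy report `|new effect|` and pass below 0.05 on the
probability scale — the relative bar is the use case's stated criterion,
the absolute bar is this package's choice since none was stated, and both
are configurable. Twenty repetitions are averaged by default; repetition
counts were not stated either, and 20 makes the Monte-Carlo spread of the
refuted effect small relative to the thresholds. A relative strategy on a
zero estimate is undefined (division by zero) and is rejected rather than
silently passed.

## Problem sizes used in validation

The shipped validation suite runs, among smaller cases: structure
recovery on 20 cohorts of n = 20 000 (SHD ≤ 4 against the 15-edge truth in
≥ 80% of seeds; measured 90–95%); CI-test calibration over 200 null
simulations at n = 2000; the Taylor/Monte-Carlo comparison on 20 random
16-12-8-2 networks at 10⁵ draws each; mediation against adjusted
regression on random 6-node linear SCMs at n = 20 000; meta-learner
recovery of a constant effect over 20 replicates at n = 5000 (relative
bias well under 10%); and the full refutation suite on a sound backdoor
estimator at n = 5000. These sizes were chosen to make Monte-Carlo error
small relative to the tolerances while keeping a full run in minutes on a
single core.

## Known limitations

* Linearity everywhere mediation is involved; no latent-variable (FCI/PAG)
  machinery, no cyclic structures.
* The Taylor engine degrades near ReLU kinks (quantified by
  `kink_margin()`) and for covariances large enough that third-order terms
  matter.
* A classifier trained to saturation breaks the Taylor engine's scale: on
  the synthetic cohort the label is a deterministic threshold of CR, so a
  long-trained network drives its logit slopes (hence the softmax
  curvature) arbitrarily high, and `½ tr(HΣ)` with the full input
  covariance can leave the [0, 1] probability scale entirely. Curves
  remain readable as trends, but for quantitatively meaningful
  expectations the network should be kept at moderate confidence (the
  README example trains to ~0.84 accuracy for exactly this reason), or
  the curvature–covariance product checked before trusting magnitudes.
* Discovery output can contain undirected leftovers; they are reported as
  undirected and excluded from path-based attribution with a warning, not
  arbitrarily oriented.
* Whether the real study let the outcome participate in discovery is
  unknown; this package excludes it (discovery runs on the features only)
  and appends it for backdoor queries, the alternative being a
  documented switch of `discover_graph(columns = ...)`.
* Whether curves should use class probabilities or pre-softmax logits was
  left open by the use case; probabilities are the default here.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(default_myopia_scm(), n = 2748, seed = 1)
model  <- train_fnn(cohort, epochs = 60, seed = 1)
graph  <- discover_graph(cohort, alpha = 0.01)
units  <- classify_units(graph)

summ  <- fit_gaussian_summary(cohort, model)
curve <- ace_isolated(model, summ, intervention_grid(cohort, "PULSE"),
                      graph = graph)
autoplot(curve)

conf <- ace_confounded(model, cohort, graph, "AL", strategy = "equal_width")
autoplot(conf)

est   <- backdoor_lm_estimator("AL", "CR",
                               covariates = as.character(
                                 backdoor_set(myopia_reference_graph(TRUE),
                                              "AL", "Myopia")))
refutation_suite(est, cohort,
                 params = list(treatment = "AL", outcome = "CR"))
```
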