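---
title: "Knowledge-weighted Lasso selection and counterfactual explanation of functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-weighted Lasso selection and counterfactual explanation of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fclasso)
```

## The problem

Resting-state functional connectivity (FC) summarizes the pairwise
dependence between the time series of brain regions: for an atlas of
$N$ regions (by default the 90 regions of the AAL atlas), each subject
is an $N \times N$ symmetric matrix of correlation-like values in
$(-1, 1)$. Classifying patients against normal controls (NC) from such
matrices is a high-dimensional, small-sample problem — the strict upper
triangle of a 90-region matrix already contains
$p = N(N-1)/2 = 4005$ edge features, typically an order of magnitude
more than the number of subjects. `fclasso` addresses two questions
around this classification task:

1. **Which edges should the classifier use?** Sparse selection with a
   weighted Lasso whose per-edge penalty factors encode external domain
   knowledge (elicited from a text-generation model or supplied from a
   file), guarded by cross-validation so that unreliable knowledge can
   never make selection worse than the plain Lasso.
2. **What would have to change for a given patient?** Diverse, proximal
   counterfactual edge adjustments against the trained classifier,
   rendered as ranked plain-language intervention reports.

Throughout the package the label convention is **1 = normal control,
0 = patient**, and sensitivity is the true-positive rate with positives
= label 1. This is the reverse of the common clinical convention and is
stated on every relevant function.

## Knowledge-weighted Lasso with a cross-validated transform

The baseline selector is the Lasso on the 0/1 labels treated as reals,

$$\hat\beta = \arg\min_\beta \tfrac12 \sum_i (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda \sum_j |\beta_j|,$$

which penalizes every edge equally. Domain knowledge enters as a vector
of strictly positive per-edge penalty scores $S = (s_1, \dots, s_p)$ —
*smaller score = stronger prior evidence = easier to select* — giving
the weighted objective

$$\hat\beta = \arg\min_\beta \tfrac12 \sum_i (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda \sum_j \omega_j |\beta_j|.$$

Scores from a language model can be wrong or hallucinated, so the
weights are not $s_j$ directly but a member of the power family
$\omega_j = s_j^\varphi$, $\varphi \in \{0, 1, \dots, \varphi_{max}\}$
(default $\varphi_{max} = 5$), with the exponent chosen by stratified
$k$-fold cross-validation (default $k = 5$) jointly with $\lambda$.
$\varphi = 0$ gives unit weights — exactly the plain Lasso — so the
minimizing cell of the CV loss surface can never have a larger CV loss
than the best plain-Lasso cell. This worst-case guarantee is asserted
programmatically on every `select_transform_cv()` call
(`guard_ok`, `guard_margin`).

Design choices that the problem statement leaves open, and how this
package resolves them:

* **Validation loss.** Mean squared error of the linear predictor
  against the 0/1 labels, consistent with the squared-error fitting
  objective; misclassification loss is available via `loss =
  "misclass"`. Classification itself is delegated to the SVM stage.
* **$\lambda$ selection.** Chosen jointly with $\varphi$ on the same
  folds, over a per-$\varphi$ log-spaced grid of 20 values spanning 3
  decades down from $\lambda_{max}$ (the smallest fully-shrinking
  $\lambda$). A fixed $\lambda$ across $\varphi$ would confound weight
  scale with shrinkage level.
* **Weight rescaling.** After the power transform, weights are rescaled
  to mean 1. This keeps $\lambda$ grids comparable across exponents
  (raw $s_j^\varphi$ magnitudes explode with $\varphi$) without
  changing relative penalization.
* **Tie-breaking.** Among CV-loss ties (within $10^{-12}$): smallest
  $\varphi$ first (least dependence on external knowledge), then
  largest $\lambda$ (sparsest model). With constant scores all
  exponents coincide and the tie resolves to $\varphi = 0$.
* **Solver.** Cyclic coordinate descent (implemented in C++) on
  centered, optionally unit-scaled features, warm-started along the
  $\lambda$ path; convergence when the largest coefficient change in a
  sweep falls below $10^{-7}$, capped at $10^5$ sweeps. Every fit can
  be certified against the weighted KKT stationarity conditions
  (`lasso_kkt_residual()`), and unit-weight fits are tested against
  glmnet and closed-form oracles.
* **Support.** Edges with $|\beta_j| > 10^{-8}$ on the standardized
  scale, ordered by decreasing magnitude. An empty support is reported,
  never silently propagated; the evaluation protocols then walk the
  chosen exponent's $\lambda$ path down to the largest value with a
  nonempty support.

## Classification and evaluation

A linear-kernel soft-margin SVM (regularization constant 1 by default)
is trained on the selected edges. The kernel is deliberately linear:
the counterfactual engine needs a differentiable, unscaled decision
value, and an affine logit $w^\top x + b$ with *prediction 1 iff logit
$\ge 0$* is the simplest contract satisfying that. The wrapper
re-orients $(w, b)$ after training so positive logits always mean class
1, independent of which class the underlying solver treated as
positive.

Evaluation reports accuracy, sensitivity and specificity in percent
from the confusion counts. Two protocols are provided, both leak-free
by construction: `kfold_protocol()` repeats transform selection (an
inner CV), support extraction and SVM training inside each outer
training fold, and `leave_one_dataset_out()` does the same with entire
held-out datasets for cross-site generalization. Each result records
the per-fold training rows and selected edges so the no-leakage claim
is auditable and is in fact replayed in the test suite.

## Counterfactual generation

For a subject $m \in \mathbb{R}^q$ on the selected edges and a target
class $\hat Y$ (default 1: patient $\to$ NC), the engine jointly
optimizes $L$ candidates (default $L = 5$) by minimizing

$$\frac{1}{L}\sum_l \max(0,\, 1 - z \cdot \mathrm{logit}(x^l))
 + \frac{\gamma_1}{L} \sum_l \mathrm{dist}(x^l, m)
 - \gamma_2 \det(K),$$

with $z = +1$ for $\hat Y = 1$ and $-1$ for $\hat Y = 0$, defaults
$\gamma_1 = 0.5$ and $\gamma_2 = 1$. The distance is the MAD-normalized
mean absolute difference over the $q$ features,
$\mathrm{dist}(x, m) = \frac1q \sum_\alpha |x_\alpha - m_\alpha| /
\mathrm{MAD}_\alpha$, with raw (unscaled) training-set MADs floored at
$10^{-3}$. Diversity is the determinant of the similarity kernel
$K_{uv} = 1/(1 + \mathrm{dist}(x^u, x^v))$: near 0 for duplicated
candidates, approaching 1 as candidates spread. A seeded uniform jitter
in $[0, 10^{-4}]$ on the diagonal, fixed for the whole run, keeps
near-singular kernels stable; its gradient uses the adjugate identity
$\partial \det / \partial K = \det(K) K^{-1}$.

The optimizer is projected (sub)gradient descent: initial step size
0.05, up to 2000 iterations, 3 restarts from $m$ plus Gaussian noise
(sd 0.05), candidates clipped to the box bounds (default $(-1, 1)$, the
FC range) after every step. A step that fails to decrease the objective
is rejected and the step size halved, so the recorded objective trace
is non-increasing. Candidates that end on the wrong side of the
boundary are flagged invalid but never dropped. Three properties are
exercised in the tests: validity flags agree exactly with the
classifier, $\gamma_1 > 0$ strictly improves proximity, and
$\gamma_2 > 0$ strictly improves pairwise separation, on matched seeds.

`sparsify_counterfactuals()` is an explicit post-processing stage, off
by default: it greedily restores features to their original values in
ascending $|\Delta|/\mathrm{MAD}$ order while the prediction stays at
the target. In practice this reduces typical candidates to one or two
changed edges. With `polish = TRUE` the surviving changes are
additionally bisected down to the smallest magnitude that keeps the
candidate valid, which makes the minimal candidate's distance match the
analytic boundary projection on linear models (the package tests this
to within 5%).

## Explanations

`explanation_request()` packages a counterfactual set for rendering.
The deterministic `template_explanation()` ranks one step per candidate
by (valid first, fewest changed edges, smallest total normalized
change) — a fixed operationalization of "effectiveness and
feasibility" — and words each step from fixed templates, so no numeric
value can appear that is not already in the diffs. `llm_explanation()`
sends the same content to a pluggable provider and parses the
requested `RANK n: OPTION k: ...` structure, falling back to the
template (with the verbatim response retained) on malformed output or
provider failure; a report is always produced. Every report carries a
research-use disclaimer: these are exploratory model readouts, not
clinical recommendations.

## Penalty-score elicitation

Prompts are a pure function of a `prompt_spec()`: system context, task
description, contrast category, a delimited block of edge names, and a
machine-readable output instruction (`name<TAB>score`, penalty
semantics: small = important). Edges are scored in chunks (default 200
names per prompt) because thousands of names in one query are
unreliable; responses are validated strictly — every requested name
must receive one positive score; out-of-range values are clipped into
$[10^{-3}, 10^3]$ (keeping all power transforms finite) with warnings;
missing names are hard errors so the caller can retry a chunk.
Temperature 0 (greedy decoding) is requested by default and responses
are cached on disk keyed by an MD5 of (provider name, prompt), so
reruns issue no provider calls. A deterministic mock provider (scores
from a seeded hash of each edge name) and a file-backed provider make
the entire pipeline runnable offline; live endpoints plug in as a
plain `function(prompt) -> text`.

## The synthetic generator

Real multi-site schizophrenia FC datasets are access-restricted, so the
package ships a first-class generator instead. Each edge has a latent
Gaussian baseline ($\mu_j \sim N(0, 0.2)$, fixed by the seed); class-1
subjects are shifted by `effect_size` on a chosen set of signal edges;
within-class noise is Gaussian (`noise_sd`); and latent values are
squashed into $(-1,1)$ by `tanh`, since FC values are correlation-like
and the counterfactual engine box-constrains to this range. Matched
score vectors emulate the knowledge provider: `informative` (strictly
smaller penalties on the signal edges), `misleading` (smaller penalties
on a disjoint random set — the hallucination scenario the CV guard
exists for), and `uniform`.

Reference conditions, chosen once as a realistic desk-scale analog of a
single-site study and used as the generator defaults: 60 subjects per
class (within the range of typical single-site case-control cohorts),
10 regions (45 edges, keeping $p$ of the same order as $n$ so selection
is genuinely sparse but tractable in seconds), 5 signal edges, unit
effect size and unit latent noise. The guard simulations run at effect
size 1; support-recovery simulations at effect size 2. These sizes are
also what the test suite and the acceptance script use, with 20 seeded
replicates per rate estimate.

What the generator deliberately does **not** emulate: inter-edge
covariance structure, site and scanner effects, demographic
confounding, or any temporal (BOLD time-series) structure — the method
consumes edge features only, so simulating those would add nothing the
package could test. Passing results on synthetic data therefore
demonstrate correctness of the algorithms under the stated model, not
clinical performance on real cohorts.

## Degenerate inputs and numerical corner cases

* Asymmetric connectivity matrices are rejected (tolerance $10^{-8}$
  absolute), naming the offending entry, rather than symmetrized —
  asymmetry indicates an upstream preprocessing error.
* The matrix diagonal is ignored, never validated: self-connectivity is
  not a feature.
* Constant features get floored MADs; zero-MAD distances stay finite.
* Folds are stratified; a class with fewer members than folds is a
  reported stratification failure, not a silent single-class fold.
* Zero valid counterfactuals after all restarts is a warning carrying
  the best achieved logits, never an empty silent result.
* All randomness flows through explicit integer seeds
  (Mersenne-Twister), and the generator, mock provider, optimizer and
  protocols are bit-reproducible under a fixed seed.

## Known limitations

* The squared-error regression on 0/1 labels is a working-model choice
  (matching the selection objective), not a calibrated probability
  model.
* The SVM's regularization constant is fixed (default 1) rather than
  nested-tuned, to keep the evaluation protocol minimal; `cost` is
  exposed for sensitivity analyses.
* Counterfactual optimization is non-convex (the diversity term); the
  engine reports the best of a few restarts, not a global optimum.
* Counterfactual edge adjustments are statements about a classifier,
  not about neurobiology; the explanation stage says so on every
  report.
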