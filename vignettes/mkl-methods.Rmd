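---
title: "Multiple kernel learning in kernelmix: models, solvers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple kernel learning in kernelmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelmix)
```

## The problem

Integrating heterogeneous data sources — say, tumour stage and age alongside
a high-dimensional expression profile — into one classifier is awkward when
the sources live on different scales and carry different kinds of structure.
Kernel methods reduce every source to the same currency: an $n \times n$
positive semidefinite similarity matrix between samples. Multiple kernel
learning (MKL) then learns, jointly with a soft-margin SVM, how much each
candidate similarity should contribute:

$$K(\eta) = \sum_{m=1}^{M} \eta_m K_m, \qquad \eta_m \ge 0,\ \sum_m \eta_m = 1 .$$

A convex combination of kernels is again a kernel, so $K(\eta)$ is a valid
input to the SVM for any feasible $\eta$. The learned weights double as an
importance score for each data source, gene set, or bandwidth — which is
often the scientifically interesting output, more than the classifier
itself.

## Kernels

Five kernel families are provided (`kernel_spec()`):

| family | formula | hyperparameters |
|---|---|---|
| linear | $x^\top y$ | — |
| polynomial | $(\nu\, x^\top y + c)^a$ | degree $a \ge 1$, scale $\nu > 0$, offset $c$ |
| radial | $\exp(-\sigma\|x-y\|^2/2)$ | bandwidth $\sigma > 0$ |
| clinical nominal | $\mathbf{1}[x = y]$ | — |
| clinical ordinal | $(r - |x-y|)/r$ | level range $r > 0$ |

Notes on conventions:

* **Radial `/2`.** Some kernel libraries parameterize the radial kernel as
  $\exp(-\sigma\|x-y\|^2)$, without the division by two. We implement the
  halved exponent as the primary definition and expose `rbf_half = FALSE`
  for the alternative, since the two conventions differ only by a factor of
  two in $\sigma$ and mixing them up silently shifts every bandwidth grid.
* **Clinical kernels on several columns** average the per-column similarity,
  which keeps entries in $[0,1]$; ordinal labels may be supplied as a level
  list, in which case codes $1..L$ are assigned in order and $r$ defaults to
  $L-1$.
* **Cosine normalization** ($K_{ij}/\sqrt{K_{ii}K_{jj}}$) is off by default
  and only offered for linear and polynomial kernels — radial, nominal and
  ordinal kernels already have unit self-similarity.
* **Composite candidates** (`kernel_combo()`) represent weighted averages of
  member kernels (for example stage and age averaged into one clinical
  candidate) so that the screening and pipeline stages can treat them like
  any other candidate.
* `validate_psd()` treats eigenvalues above $-10^{-13}$ times the spectral
  scale as rounding noise; anything worse gets a diagonal jitter
  ($10^{-8}$ by default) and is reported, never silently accepted.

## The SVM core

The soft-margin dual

$$\max_\alpha\ \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j y_i y_j K_{ij}
\quad \text{s.t.}\quad 0 \le \alpha_i \le C,\ \textstyle\sum_i \alpha_i y_i = 0$$

is solved by sequential minimal optimization with maximal-violating-pair
working-set selection (compiled code; default KKT tolerance $10^{-6}$). The
bias is averaged over unbounded support vectors, falling back to the KKT
interval midpoint when all support vectors sit on the box. Class labels are
encoded lexicographically (first class $\to -1$), ties in the decision value
go to the positive class, and the mapping is recorded in every model.

Cross-validation (`cross_validate_svm()`) uses stratified folds (class
counts per fold differ by at most one) and reports the accuracy of each
(kernel, C) cell **pooled over folds** — total correct over $n$ — rather
than the mean of per-fold accuracies. With unequal fold sizes the plain mean
is biased; pooling guarantees, in particular, that a majority-class
predictor scores exactly the no-information rate, which the screening rule
below depends on. The default cost grid is
$\{0.01, 0.1, 1, 10, 100\}$: neither the wrapper solvers nor the screening
stage has a canonical cost, so a log-spaced grid around 1 is the neutral
choice.

## Wrapper solvers: SEMKL and SimpleMKL

Both wrappers minimize over the simplex the optimal dual value
$J(\eta)$ of the combined kernel, alternating a full SVM solve with a
weight update.

**SEMKL** updates weights in closed form,
$\eta_m \leftarrow \|f_m\| / \sum_k \|f_k\|$ with
$\|f_m\|^2 = \eta_m^2\, \alpha^\top (y y^\top \circ K_m)\, \alpha$ — the
update that makes the Cauchy–Schwarz bound on the weighted-norm objective
tight. It stops when $\max_m |\Delta\eta_m| < 10^{-4}$ (default) or after
100 iterations. Near a vertex of the simplex the iteration converges only
linearly, so the oracle-equivalence tests run it with a tighter tolerance
and a larger budget; the defaults favour the benchmark's interactive speed.

**SimpleMKL** takes reduced-gradient steps: the SVM at the current $\eta$
yields $\partial J/\partial \eta_m = -\tfrac12 \alpha^\top (yy^\top \circ
K_m) \alpha$; the gradient is reduced against the largest-weight component
(ties broken by lowest index), directions that would push a zero weight
negative are clipped, and the step size comes from a line search in which
every candidate costs one SVM solve. Two details matter in practice:

* *Full steps to the boundary first.* While the objective at the **maximal**
  feasible step keeps improving, that step is taken outright, the weight
  that hits zero is zeroed exactly, and the direction is re-reduced. Without
  this, a dying weight is only ever multiplied by a factor in $(0,1)$ — the
  iteration crawls toward the boundary without reaching it and stalls at a
  suboptimal face. Golden-section search on the remaining segment, with a
  backtracking fallback that accepts the first improving step, then refines.
* *Stopping.* The relative duality gap
  $(\max_m S_m - \sum_m \eta_m S_m)/2|J|$ falls below `tol_gap`
  (default 0.01), or the SVM-solve budget (default 200) is exhausted;
  `converged` reports which. Weights below $10^{-8}$ are zeroed and the
  vector renormalized.

Both solvers start from uniform weights. On small random problems the two
reach the same objective to within $10^{-3}$ relative, and neither is beaten
by an exhaustive $0.05$-step simplex grid — both facts are enforced by the
test suite against brute-force oracles (a generic interior-point QP for the
SVM dual, exhaustive enumeration for the grid).

## The sparse solver: DALMKL

For large kernel menus the wrappers' one-SVM-per-step cost adds up, and
their simplex weights are rarely exactly sparse. The third solver attacks
the block-1-norm regularized primal

$$\min_{f_1..f_M,\,b}\ \frac1n \sum_{i=1}^n \ell\!\left(y_i,\ \textstyle\sum_m f_m(x_i) + b\right)
 + C \sum_{m=1}^M \|f_m\|_{\mathcal H_m},$$

with hinge or logistic loss, by an augmented-Lagrangian method on the dual
of a proximal reformulation. Writing $f_m = K_m \beta_m$ and
$\|f_m\|^2 = \beta_m^\top K_m \beta_m$, each outer iteration minimizes a
smooth inner objective in the dual vector $\alpha$ in which every kernel
block enters through the soft-threshold operator
$\mathrm{ST}_{\gamma C}(q_m) = \max(0,\ 1 - \gamma C/\|q_m\|)\, q_m$
applied to $q_m = \beta_m + \gamma\alpha$ (norms taken in the $K_m$ metric,
so only Gram matrices are ever needed). Blocks whose $K_m$-norm falls below
$\gamma C$ contribute nothing to the inner gradient or Hessian and update to
**exactly** zero — inactive kernels are bitwise zero in the solution, not
merely small. The inner problem is solved by projected Newton steps: the
hinge conjugate is linear on the box $y_i\alpha_i \in [0,1]$ (non-smooth
only on the boundary, which the projection respects), the logistic conjugate
is an entropy barrier that keeps iterates interior.

Numerical choices:

* **Mean loss.** The penalty $C$ is weighed against the *average* loss.
  Against a summed loss the recommended penalties $\{0.5, 0.05, 0.005\}$
  are negligible at $n \sim 100$ (no kernel is ever pruned and all three
  values give identical fits); against the mean loss they span
  strong/selective/permissive pruning, which is the behaviour those three
  values are recommended for. Internally the whole objective is scaled by
  $n$, which changes nothing about the minimizer.
* **Proximity schedule with an acceptance guard.** $\gamma$ starts at 1 and
  grows fourfold per outer iteration, capped at $10^6$. A large $\gamma$
  makes the inner problem extremely ill-conditioned, and an inexact inner
  solve can then *increase* the primal objective; an outer step is therefore
  committed only if the primal objective does not increase, otherwise
  $\gamma$ is shrunk fourfold and the step retried. This keeps the outer
  trace monotone by construction (a property the tests assert) and in
  practice lets $\gamma$ find the largest value the inner Newton solver can
  support.
* **Stopping.** Successive outer objectives within `outer_tol`
  ($10^{-6}$ relative) terminate the fit; `converged` is honest about
  budget exhaustion.
* **Cost mapping.** The wrapper and DAL formulations scale their costs
  differently, so `estimate_wrapper_cost()` returns $\max_i |\alpha_i|$ of
  the DAL dual — the wrapper cost at which the box constraint is tight at
  the DAL solution's largest dual coefficient. No closed-form equivalence
  exists between the two problems; this mapping is a declared convention,
  validated by a cross-solver test requiring $\ge 95\%$ held-out label
  agreement between DAL-hinge and SimpleMKL at the mapped cost.
* Reported DAL "weights" are the RKHS block norms normalized to sum to one,
  so heatmaps are comparable across all three solvers.

## Prioritization: features, kernels, outcomes

The recommended experiment is a pipeline (`run_workflow()`): split the
samples (70/30 by default, stratified), rank features on the training rows
only, build the kernel menu, screen each candidate by cross-validated SVM,
fit MKL on the survivors, and evaluate once on the held-out rows.

* **Feature ranking** uses the Welch $t$-test (the unequal-variance variant
  is the safer default when only "a $t$-test" is specified) or the Wilcoxon
  rank-sum test. Constant features cannot be tested; they are kept with
  $p = 1$ and flagged rather than silently dropped, so column bookkeeping
  downstream never shifts.
* **Kernel screening** keeps, per candidate, its best (shape,
  hyperparameter, cost) cell by CV accuracy and eliminates candidates whose
  best accuracy does not *exceed* the no-information rate. Equality is
  elimination: a kernel that only reproduces the majority-class guess
  carries no usable signal, and with pooled CV accuracy the majority-class
  predictor lands on the NIR exactly. An empty survivor set raises a typed
  condition (`no_surviving_kernels`) — the pipeline halts rather than fit
  MKL on nothing.
* **Gene-set kernels** instantiate one spec per set from a GMT file,
  restricted to the measured genes; empty intersections are dropped with a
  warning count. Screening then assigns each set its best shape and cost,
  and the MKL weight of each surviving set is its importance score.
* **Survival dichotomization** excludes right-censored patients first, then
  picks a cutoff among midpoints of consecutive distinct event times whose
  survivor proportion lies in $[0.4, 0.6]$, preferring the proportion
  closest to $0.5$ (ties: the smaller cutoff). The band boundaries are
  inclusive. This is deliberately naive — the censoring mechanism is
  ignored, so the resulting labels are biased toward observed deaths; the
  package provides it because it is the standard preprocessing step for
  this kind of analysis, not because it is good survival methodology.

## What the synthetic generators do and do not emulate

**Two-group Gaussian benchmark.** Group 1 is fixed at mean $(5,5)$ with
identity covariance; group 2 moves from $(-4,-4)$ to $(4,4)$ in unit steps
with covariance off-diagonal $-0.5$; 50 training and 50 test observations
per group, drawn independently; candidate kernels are radial with
$\sigma_1 = 2$ (wiggly) and $\sigma_2 = 0.04$ (smooth). One published
account of this benchmark prints $0.04$ in the text and $0.05$ in a figure
caption for the smooth kernel; we default to $0.04$ and leave the value
configurable. The nine printed configurations never actually coincide —
group 2 at $(4,4)$ is still $\sqrt2$ away from group 1 — so a tenth,
equal-means configuration (covariances still differ) is appended by default
as the genuinely "completely overlapping" case; the chance-level acceptance
check uses it. Expected behaviour, asserted over 30 replicates per
configuration: every solver is essentially perfect when the groups are far
apart, sits at $0.5 \pm 0.1$ under equal means, and the wiggly kernel's mean
weight increases monotonically with overlap (Spearman $\rho \ge 0.9$ for
both wrappers). The wrapper cost is fixed at $C = 1$ and DAL at $C = 0.05$
for the sweep — no cost is stated for this experiment anywhere we could
follow, and these package defaults reproduce all three qualitative
behaviours simultaneously.

**Multi-source omics study.** `gen_multiomics()` draws tumour stage
(4 ordinal levels) and age, links them to a binary prognosis through a
logistic model (coefficients 0.6 per stage level and 0.5 per age SD), shifts
8 of 200 expression features by 0.5 SD between prognosis groups, and draws
survival times from a two-component log-normal (medians about one vs four
years, $\sigma_{\log} = 0.5$) with 20% independent uniform censoring. The
defaults were calibrated once, in a pilot, to the regime the method is for:
each source alone supports roughly 60–65% held-out accuracy and their
integration roughly 67% — two individually weak, complementary sources.
Asserted behaviour over 20 seeds: the clinical+expression MKL fit beats both
single-source fits on average.

What these generators do **not** emulate: real platform noise and batch
effects, correlated expression blocks, informative censoring, multi-class
outcomes, or the sample sizes of consortium datasets. A green test suite
says the algorithms behave as described under the stated generative models;
it says nothing about any particular cancer dataset.

**Problem sizes in the test suite.** The oracle-equivalence checks run 20
random instances at $n \le 25$, $M \le 3$ against exhaustive and
interior-point oracles; the benchmark checks run the full
10-configuration × 30-replicate sweep; sparsity and screening checks use 20
seeds at $n = 60$; the integration check 20 seeds at $n = 160$, $p = 200$.
These sizes were chosen so the whole suite completes in minutes while
keeping every Monte-Carlo criterion comfortably powered. The screening check
gives the uninformative candidate a 20-feature pure-noise block (a
gene-set-sized kernel): screening exists to discard exactly such blocks, and
a well-sized block is also the statistically clean case — with only two
noise features the best-over-grid CV accuracy fluctuates above the NIR by
chance in a nontrivial fraction of seeds, which is a property of
small-sample CV, not of the elimination rule.

## Known limitations

* Binary classification only; no support vector regression, no multi-class.
* Simplex-constrained ($L_1$) weights only; no $L_p$ or elastic-net MKL.
* Kernel de-duplication (alignment, redundancy filtering) is out of scope;
  heavily redundant menus dilute wrapper-method weights across duplicates
  (predictions are unaffected — a test asserts this).
* The survival path ignores censoring by design (see above).
* Gram matrices are dense $n \times n$; the implementation targets cohort
  sizes in the hundreds, not single-cell scale.
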