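---
title: "Sparse-group regularization paths by proximal gradient descent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-group regularization paths by proximal gradient descent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgpath)
```

## The model and its penalty

`sgpath` estimates linear models with two effect blocks,

$$
\min_{(b,\,u)}\;\frac{1}{2n}\lVert y - Xb - Zu\rVert_2^2
 + \alpha\lambda \sum_{j=1}^{p} \omega_j^F |u_j|
 + (1-\alpha)\lambda \sum_{l=1}^{L} \omega_l^G \lVert u^{(l)}\rVert_2 .
$$

The unpenalized block $b$ absorbs effects that should never be shrunk — an
intercept, sex, batch, known covariates. The penalized block $u$ carries the
high-dimensional features (methylation probes, SNP dosages, expression
values), partitioned into $L$ non-overlapping groups known before fitting,
e.g. from linkage disequilibrium blocks or from the measurement modality.
The objective is jointly convex in $(b, u)$; its minimizers are exactly
sparse because the penalty is non-smooth at zero.

Three assumptions matter in practice. First, groups are disjoint — features
belonging to several pathways must be resolved to one group (or duplicated
as distinct columns) before fitting. Second, the design is dense and
in-memory. Third, the model is Gaussian-linear; generalized linear and
survival variants are out of scope.

### Weights

Per-feature weights $\omega^F_j > 0$ rescale each feature's penalty. Group
weights are derived, not free parameters:
$\omega^G_l = \sqrt{p_l \overline{\omega^F}_l}$ with
$\overline{\omega^F}_l$ the mean feature weight in group $l$. Unit feature
weights therefore recover the classical $\sqrt{p_l}$ group factor, and the
whole weighted problem collapses to the standard sparse-group lasso. Two
builders cover the common cases:

* `ipf_weights(sizes, factors)` assigns one penalty factor per contiguous
  modality block, which with $\alpha = 1$ is the IPF-lasso (integrative
  lasso with penalty factors). Only the *ratios* of factors matter: a
  common multiplicative constant $c$ in the weights is exactly equivalent
  to rescaling $\lambda$ by $c$, an identity the test suite verifies to
  $10^{-8}$. Classical IPF notation writes per-modality penalties
  $\lambda_m = 2n\lambda\omega^F$; the $2n$ is absorbed into the grid here.
* `maf_weights(maf)` gives $2\sqrt{\mathrm{MAF}(1-\mathrm{MAF})}$, the
  Hardy–Weinberg standard deviation of an allele count, so common variants
  are penalized more than rare ones. MAF must lie in $(0, 0.5]$: a zero
  weight would silently unpenalize its feature.

When both $\alpha < 1$ and non-trivial feature weights are supplied, the
group-weight formula above is applied to whatever $\omega^F$ the user
passes; no special interaction is defined.

## The solver

### Proximal gradient descent

Each penalty value is solved by proximal gradient descent (PGD): a gradient
step on the smooth least-squares term,
$\nabla = (-X^\top r/n, -Z^\top r/n)$ with $r = y - Xb - Zu$, followed by
the proximal map of the penalty. For the sparse-group penalty the proximal
map is available in closed form and separates over groups: soft-threshold
each coordinate at $t\alpha\lambda\omega^F_j$, then apply group shrinkage
at $t(1-\alpha)\lambda\omega^G_l$, where $t$ is the step size. For a sum of
$\ell_1$ and group-$\ell_2$ penalties on the same block this composition
*is* the exact proximal operator; the test suite pins this against an
independent enumeration-based minimizer of the proximal objective rather
than trusting the algebra. The unpenalized block has the identity prox —
it is simply excluded from the map. PGD is used in its plain form: no
momentum or acceleration, which keeps every iteration monotone in the
objective and the implementation easy to certify.

### Backtracking line search

The step size is found by backtracking: a candidate step $t$ is accepted
when the quadratic majorization
$f(x^+) \le f(x) + \nabla f(x)^\top (x^+ - x) + \tfrac{1}{2t}\lVert x^+ -
x\rVert^2$ of the smooth term holds, and otherwise multiplied by
`shrink = 0.5` and retried. Acceptance is guaranteed once
$t \le n/\lVert Z \rVert_2^2$, so the search always terminates (a step
underflow below $10^{-30}$ raises an error rather than looping). The
accepted step is carried from one iteration to the next and, along the
path, from one penalty to the next: steps only shrink, which wastes no
function evaluations re-probing large steps, and since every accepted step
satisfies the majorization the converged solutions do not depend on this
carrying policy beyond the stopping tolerance. `step0 = 1` and
`shrink = 0.5` are conventional choices; neither is critical.

### Stopping rule

Iteration stops when

$$
\frac{\lVert (b,u)^{[k]} - (b,u)^{[k-1]} \rVert_\infty}
     {\lVert (b,u)^{[k]} \rVert_2} \le \varepsilon_{rel},
$$

the *relative accuracy*: the max-norm gain of the last iteration scaled by
the size of the current estimate, evaluated on the concatenated $(b, u)$
vector. At least one iteration is always performed. If the current iterate
is identically zero the criterion counts as met only when the last step
also changed nothing (otherwise a zero iterate passing through the origin
could stop the solver spuriously). Reaching `max_iter` flags
`converged = FALSE` in the diagnostics but is not an error. Each solve also
reports a KKT residual — the maximum violation of the subgradient
stationarity conditions — as an independent certificate: it is computed
from the data and the solution only, not from the iteration history.

### The penalty grid and warm starts

$\lambda_{max}$, the smallest penalty at which the zero solution for $u$ is
optimal, is computed exactly from the optimality conditions at
$(b_0, 0)$, where $b_0$ is the least-squares fit on $X$ alone
(minimum-norm if $X$ is rank deficient; with no $X$ the baseline residual
is $y$). With $g^{(l)} = Z^{(l)\top} r_0/n$ the critical value is
$\max_j |g_j|/\omega^F_j$ for $\alpha = 1$ and
$\max_l \lVert g^{(l)}\rVert_2/\omega^G_l$ for $\alpha = 0$; for
intermediate $\alpha$ each group's critical value solves
$\lVert S(g^{(l)}, \alpha\lambda\omega^F)\rVert_2 =
(1-\alpha)\lambda\omega^G_l$, a strictly monotone scalar equation solved by
bisection to relative tolerance $10^{-10}$ (the upper end of the final
bracket is returned, so the computed $\lambda_{max}$ never falls below the
true boundary and the first path point is exactly sparse). A response with
$Z^\top r_0 = 0$ — e.g. $y$ in the column space of $X$ — has no finite
path top and raises a degenerate-problem error.

The grid is log-equispaced, $\lambda_k = \lambda_{max}\xi^{k/(K-1)}$, and
solved in decreasing order with warm starts: each solution (and its
accepted step size) initializes the next solve. Warm starts change only
speed, not solutions — the suite checks warm and cold paths agree per
penalty to $10^{-5}$ relative in objective.

## Defaults

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.95 | mostly-lasso mixing with a small group pull |
| `nlambda` | 50 | grid length |
| `lambda_min_ratio` (ξ) | 0.001 | $\lambda_{min}/\lambda_{max}$ |
| `rel_acc` ($\varepsilon_{rel}$) | $10^{-4}$ | stopping threshold |
| `max_iter` | 1000 | per penalty value |
| `step0`, `shrink` | 1, 0.5 | line-search controls |

These are the standard settings for sparse-group analyses of genomic data;
tightening `rel_acc` sharpens sparsity at the cost of iterations (solutions
barely inside the boundary of zero get resolved to exact zeros only as the
iterates converge), which is worth knowing when the non-zero count itself
is a quantity of interest.

No implicit standardization or centering is performed: the objective is
solved exactly as written on the input scale, and an intercept is whatever
ones column the user puts into $X$. An optional `standardize` flag scales
$Z$ columns to unit standard deviation before fitting and maps estimates
back to the input scale afterwards; it is off by default so that results
are never silently on a different scale than the inputs.

## The synthetic generator

`sgp_simulate()` draws grouped Gaussian designs with within-group
correlation $\rho$ (via a shared group factor: marginal variance 1,
correlation exactly $\rho$ within, 0 across), effects $\pm$`effect_size`
concentrated on a few groups, an optional ones-column covariate block with
unit coefficients, and additive Gaussian noise. Defaults — $n = 100$, 10
groups of 6, 2 active groups, $\rho = 0.3$, unit effects and unit noise —
describe a mid-difficulty recovery regime: enough signal that the active
groups are recoverable, enough correlation and noise that the problem is
not trivial. Train/validation splitting is the caller's job: generate twice
with different seeds, passing the first call's `truth` into the second so
both share the generating coefficients.

The generator emulates the *structure* the sparse-group lasso exploits —
many correlated features, group organization, group-level sparsity,
$p \gg n$ feasible — not the marginal distributions of any particular assay
(methylation beta values are bounded and bimodal, genotype dosages are
discrete; neither is imitated). Recovery results on these problems
therefore validate the optimizer and the selection machinery, not
field-specific preprocessing choices.

The study sizes used by the test suite and by `scripts/acceptance.R` —
instances up to $n = 30$, $p = 15$ against the generic convex-solver
oracle, 200 proximal-operator cases, and 20 replicated recovery runs at
$n = 100$, $p = 60$ — were chosen so the whole suite certifies every
component at tight tolerances while remaining quick to run on one CPU.

## Numerical choices and edge cases

* **Exact zeros.** Sparsity comes from the proximal map, which thresholds
  to exact floating-point zero; non-zero counts are exact counts, no
  epsilon involved.
* **Majorization slack.** The line-search acceptance and the monotone-trace
  guarantee carry a $10^{-12}$-scale slack for floating-point roundoff.
* **Ties.** Hold-out evaluation picks the *first* minimizer of the MSE
  curve; group relabelling preserves first-appearance order, so outputs
  are deterministic for identical inputs.
* **Degenerate inputs.** Empty groups, non-positive weights, dimension
  mismatches, non-finite entries, MAF outside $(0, 0.5]$ and unknown or
  duplicated feature identifiers in the text inputs each raise a distinct
  condition class (`sgp_dimension_error`, `sgp_weight_error`, ...), which
  the command-line front end maps to a named error on stderr and a
  non-zero exit status.
* **$K = 1$ and $\xi = 1$** are valid grid requests (a single point and a
  constant sequence, respectively).

## Limitations

Only Gaussian linear models; groups must partition the features (no
overlap); designs are dense in-memory matrices; no cross-validation driver
is included (the hold-out evaluator plus two generator calls cover the
common case, and users with folds can loop `sgp_fit`); no inference —
coefficients come with no standard errors, and the selected support is not
a hypothesis test. For per-modality penalty-factor tuning, the practical
recipe is a small grid over factor ratios (e.g. $2^{-3} \ldots 2^3$),
refitting with `ipf_weights()` and picking the ratio by validation MSE —
the factors are weights, so this costs one path per candidate ratio.
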