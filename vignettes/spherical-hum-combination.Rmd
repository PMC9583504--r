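---
title: "Combining ordinal-outcome biomarkers by spherically constrained maximization of the empirical HUM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining ordinal-outcome biomarkers by spherically constrained maximization of the empirical HUM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem and the model

Many clinical questions reduce to predicting an *ordered* categorical
outcome — a toxicity grade, a disease stage, a severity scale — from a panel
of continuous measurements. Given markers
$\mathbf{X} \in \mathbb{R}^d$ and $M$ ordered outcome categories with
category-specific distributions $F_1, \dots, F_M$, a linear risk score
$\beta^T \mathbf{X}$ discriminates the categories well when scores drawn
from higher categories tend to exceed scores from lower ones. The natural
accuracy functional is the **hypervolume under the ROC manifold**,

$$D(\beta) = P\!\left(\beta^T \mathbf{X}_M > \cdots > \beta^T \mathbf{X}_1\right),$$

which reduces to the AUC for $M = 2$ and the volume under the ROC surface
for $M = 3$. Its plug-in estimate from a sample
$\{\mathbf{X}_{j i_j}\colon j = 1, \dots, M,\ i_j = 1, \dots, n_j\}$ is the
**empirical HUM**

$$D_E(\beta) = \frac{1}{n_1 \cdots n_M} \sum_{i_1} \cdots \sum_{i_M}
  I\!\left(\beta^T \mathbf{X}_{M i_M} > \cdots > \beta^T \mathbf{X}_{1 i_1}\right),$$

implemented by `ehum()`. Because $D_E(\beta) = D_E(a\beta)$ for every
$a > 0$, the direction is identified only up to positive scaling, and the
estimation problem is posed on the unit sphere:

$$\hat\beta = \arg\max_{\|\beta\| = 1} D_E(\beta).$$

$D_E$ is piecewise constant in $\beta$ (it changes only when two subject
scores swap order), hence discontinuous, non-differentiable, and typically
multi-modal. Gradient methods are useless and local searches stall on
plateaus; the package therefore ships a global, derivative-free pattern
search specialized to the sphere (`scor_maximize()`).

Two surrogate objectives are provided for the multi-category case, built
from the adjacent-pair exceedance probabilities
$p_j = P(\beta^T\mathbf{X}_{j+1} > \beta^T\mathbf{X}_j)$: their mean
$P_A(\beta)$ (`ulba_pa()`) and their minimum $P_M(\beta)$ (`ulba_pm()`).
They sandwich the HUM,
$\max\{0, (M-1)P_A - (M-2)\} \le D \le P_M$, coincide with the AUC when
$M = 2$, and are cheaper and often easier landscapes to search; maximizing
$P_A$ is a good default for $M \ge 3$. All three objectives use strict
inequalities, so tied scores count as failures; with continuous markers
ties occur only on measure-zero sets of $\beta$, but heavily rounded data
can make the objectives non-smooth in ways the optimizer simply treats as
additional plateaus.

### Evaluation

`ehum()` does not enumerate the $\prod_j n_j$ tuples. Scores are computed
per category, and a dynamic program over categories counts, for each
observation, the number of strictly increasing chains ending there, using
sorting plus prefix sums — $O(\sum_j n_j \log n_j)$ per evaluation. The
test suite keeps an independent brute-force enumerator and checks equality
on random instances up to $10^5$ tuples, including tied data.

## The spherical pattern search

From the current unit-norm solution $\beta$, one iteration perturbs each
coordinate $i$ by $\pm s$ (the current step size). To return to the sphere,
a common adjustment $t$ is added to the other coordinates; writing $m$ for
the number of adjusted coordinates, $B = \sum_{k \ne i}\beta_k$ and $Z$ for
the squared mass of coordinates zeroed by the sparsity rule, $t$ solves

$$m t^2 + 2 B t + \left(2 s \beta_i + s^2 - Z\right) = 0,$$

implemented in `adjustment_step()`. Of the two roots we always take the one
of smaller absolute value: that root vanishes as $s \to 0$, so small steps
make small moves — the property that lets a decaying step size converge.
(The closed-form "$+$" root has this property only when $B > 0$; selecting
by magnitude extends it to every sign pattern.) A negative discriminant
means no on-sphere move exists at this step size — geometrically, the
perturbed coordinate would leave the unit disc; the direction's *local*
step is then divided by the decay rate $\rho$ until a real root appears,
and abandoned for the iteration if it falls below the threshold $\phi$
first. For any direction with $B \ne 0$ finitely many halvings suffice,
which the suite verifies on a thousand random configurations.

The $2d$ candidates plus the incumbent are compared and the best point
becomes the new solution. Two details matter on piecewise-constant
objectives:

* **Ties move.** A candidate whose value *equals* the incumbent's is
  adopted (candidates are scanned in the fixed order $1^+, 1^-, 2^+,
  \dots$, and the first best wins, so everything stays deterministic).
  Equal-valued moves walk along flat plateaus instead of idling on them,
  which is where most of the global-search power on empirical-HUM
  landscapes comes from.
* **Decay on stagnation.** When the iteration improves the value by less
  than `tol_fun`, the step size is divided by $\rho > 1$; a *run* ends once
  $s < \phi$. Runs restart at the full initial step from the current
  solution, so each run re-probes distant points around the best point
  found so far.

The search stops when two consecutive runs return the identical solution,
or — because tie moves can relocate the solution indefinitely at constant
value — after `stall_runs` consecutive runs without improvement, or at
`max_runs`. The incumbent value is non-decreasing across iterations and
runs by construction, and every point ever evaluated is unit norm.

### Tuning parameters

| parameter | default | role |
|---|---|---|
| `s_init` | 2 | initial/per-run step size; 2 spans the sphere's diameter, so early probes are genuinely global |
| `rho` | 1.5 | geometric step decay; slower decay means more distinct probe radii per run (a thorougher, slightly costlier search than e.g. 2) |
| `phi` | 1e-6 | step threshold ending a run; sets the final angular resolution |
| `tol_fun` | 1e-6 | improvement below which the step decays; with empirical objectives whose jumps are $\ge 1/\prod n_j$, any value well below that jump size behaves identically |
| `lambda` | 0 | sparsity threshold: coefficients below it are zeroed before each move (off by default) |
| `max_iter`, `max_runs` | 50000, 1000 | safety caps; normally never binding |
| `stall_runs` | 10 | stop after this many non-improving runs; raising it buys more plateau exploration at proportional cost |

These defaults are this package's own calibration: they were chosen so that
on two-dimensional empirical-AUC problems — where an exhaustive angular
grid certifies the global maximum — the search recovers the certified
optimum in the large majority of random instances at a cost of a few
thousand objective evaluations (the acceptance suite measures exactly
this). No deterministic single-start search can *guarantee* the global
maximum of a piecewise-constant multi-modal function: a plateau narrower
than the probe pattern can always hide. Users worried about a specific
dataset can restart `scor_maximize()` from several starting vectors and
keep the best solution.

Degenerate cases are handled explicitly: $d = 1$ reduces the candidate set
to the two poles $\pm 1$; a start vector whose norm is off unit (e.g. a
rounded reported solution) is normalized with a warning; when the sparsity
rule zeroes every other coordinate, the only on-sphere moves are the poles
of coordinate $i$.

## Comparator estimators

Three baselines, each normalized to unit norm on output:

* `nm_maximize()` — the first coefficient is anchored at $\pm 1$ (the sign
  with the better single-marker EHUM) and the remaining $d-1$ coefficients
  are optimized unconstrained by Nelder-Mead (`stats::optim`, iteration cap
  $200(d-1)$), exploiting scale invariance. The original approach used a
  different simplex implementation whose tolerances are not recorded, so
  this comparator is a declared approximation.
* `step_down()` — markers ranked by individual EHUM; the best marker's
  coefficient fixed at $\pm 1$; each further coefficient fitted one at a
  time by a 201-point grid on $[-5, 5]$ refined by golden-section search.
  Grid ties are broken toward the smallest coefficient magnitude so
  uninformative markers are not handed arbitrary weight. The inner 1-D
  routine of the original description is likewise unrecorded; the grid +
  refinement stands in for it.
* `min_max()` — each subject is reduced to (max, min) of its $d$ marker
  values, and the single free direction of the 2-dimensional combination
  is found by dense search over 2000 angles. After the reduction the
  search cost is independent of $d$. For $M \ge 3$ the same reduction is
  used with the multi-category objectives.

## The scenario generators and what they do (not) emulate

`generate_scenario()` reproduces three designs used for benchmarking, with
category index $i = 0, \dots, M-1$ and marker index $j = 1, \dots, d$:

1. independent $d$-variate normals, means
   $\mu_{ij} = (-1)^j\, i\,(1 + 0.1(j-1))$, identity covariance —
   separation grows with the category index, alternating in sign across
   markers;
2. the same means with covariance $a_{st} = 0.5^{|s-t|}$ — correlated
   markers;
3. independent shifted Weibull margins with scale $\lambda_i = i + 1$,
   shape $k_j = 0.5j$ and location $\gamma_j = (-5)^j$ — skewed,
   heavy-tailed for small $j$, with wildly different marker locations and
   category information only in the scale.

"Multivariate Weibull" is interpreted as independent coordinates: only
marginal parameters are specified in the design, and no coupling is
stated. The train/test harness `run_experiment()` draws a training set,
fits by the chosen method/objective, draws an independent test set of the
same design, and records the *test-set* EHUM, so reported means are free of
optimization-induced overfitting. Dispersion is reported both as the SD
across replications and as SD$/\sqrt{\text{reps}}$.

These generators emulate location/scale-separated, moderately
low-dimensional panels with known truth. They do not emulate: mixed
marker scales needing standardization, missing data, label noise,
covariate-dependent category prevalences, or markers whose relation to the
outcome is non-monotone. Passing the simulation benchmarks therefore
certifies the estimation machinery, not performance on any particular
clinical dataset.

For the normal scenarios `scenario_optimal_direction()` returns the
population-optimal direction $\Sigma^{-1}(\mu_1 - \mu_0)$ (for $M = 2$),
used by the parameter-recovery and MSE checks; `coefficient_mse()`
sign-aligns each estimate with the truth before averaging squared
distances, since $\beta$ and $-\beta$ parameterize the same direction.

## Clinical post-processing

* `greedy_correlation_filter()` — repeatedly drops the marker with the
  highest mean absolute correlation until all pairwise $|r|$ are below the
  threshold (default 0.8); ties take the earliest column; constant columns
  are an error rather than silently undefined.
* `youden_cutpoints()` — for each adjacent split of the ordered categories,
  the threshold maximizing sensitivity + specificity − 1 over the midpoints
  of adjacent sorted unique scores plus the two out-of-range thresholds
  (where the index is exactly 0); ties take the smallest threshold. With
  $M \ge 3$ the single summary value is the *mean* of the per-split maxima
  — an interpretation choice, since no standard aggregation exists; the
  per-split values are always reported alongside.
* `bootstrap_ci()` — resampling is stratified within outcome categories,
  preserving the ordered-group design and guaranteeing no category empties.
  Intervals are normal-theory, $\widehat{\text{HUM}} \pm z_{\alpha/2}
  \widehat{\text{se}}_B$; coefficient replicates are sign-aligned to the
  point estimate before the standard error is taken.
* `collapse_categories()` — order-preserving merging of grades (e.g.
  severity grades 2–4 into one class); non-monotone mappings are rejected.

## Problem sizes used by the checks

The acceptance suite and `scripts/acceptance.R` recompute benchmark cells
at their full design: 100 train/test replications per cell with per-class
sizes 15–30 and $d$ from 5 to 20. Property checks use 1000 random
instances (objective bounds, adjustment-root existence), 50 random
two-dimensional problems against a 20,000-point angular grid, 50
replications per sample size for the MSE trend, and a single $n =
500$/class fit for parameter recovery. On one CPU the full test suite runs
in a few minutes; the acceptance script in about three.

## Known limitations

* Global optimality is heuristic, not certified (see the tuning section);
  on the certified two-dimensional problems a small minority of instances
  end one misordered tuple short of the grid optimum.
* The EHUM at the fitted $\hat\beta$ on the *training* data is optimistically
  biased, increasingly so for small $n$ and large $d$; use the train/test
  harness or the bootstrap for honest accuracy.
* The surrogate $P_A$ is a bound-related objective, not the HUM itself:
  for $M \ge 3$ its maximizer can differ from the HUM maximizer.
* Only linear score functions are considered, and the category order is
  taken as given input — no orientation auto-detection beyond the
  per-marker sign choice in starting values and rankings.
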