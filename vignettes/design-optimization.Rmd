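---
title: "Cost-optimal design of exposure assessment studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-optimal design of exposure assessment studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expodesign)
library(dplyr)
```

## The design problem

Epidemiological exposure studies commonly collect data through a balanced
nested hierarchy: $n_s$ subjects, $n_d$ measurement occasions (e.g. days)
per subject, and $n_q$ sampling quanta (minutes, work cycles) per occasion.
With the usual random-effects decomposition of exposure variability into
between-subjects, between-occasions-within-subject and within-occasion
components $(s^2_{BS}, s^2_{BD}, s^2_q)$, the "mean of means" estimate of
the group mean exposure has variance

$$s^2_\mu(n_s, n_d, n_q) \;=\; \frac{s^2_{BS}}{n_s} +
\frac{s^2_{BD}}{n_s n_d} + \frac{s^2_q}{n_s n_d n_q}.$$

Data collection costs money, and the marginal cost of one more unit need
not be constant: late recruits may need more persuading, equipment wears
out, subjects get used to the protocol. The package models each stage with
a power law, giving total variable cost

$$c(n_s, n_d, n_q) \;=\; \pi_s n_s^{\alpha} + n_s \pi_d n_d^{\beta} +
n_s n_d \pi_q n_q^{\gamma},$$

where the $\pi$ are unit costs and $\alpha, \beta, \gamma > 0$ are the
exponents (1 = linear, above 1 increasing marginal cost, below 1
decreasing). The design question is: given the variance components, the
cost model, and a budget $R$ (fixed costs already deducted), which integer
design minimizes $s^2_\mu$ subject to $c \le R$?

## The two-stage reduction

The quantum count is often not a free choice (whole-day measurements,
fixed logger schedules), so the package optimizes over $(n_s, n_d)$ with
$n_q$ fixed. [reduce_stages()] folds the third stage away exactly:
$s^2_{\mu WD} = s^2_q / n_q$ becomes the variance of a single-occasion
estimate and $c_q = \pi_q n_q^{\gamma}$ the fixed cost of the
within-occasion data. Every function in the package then works with the
two-stage objective
$s^2_\mu = s^2_{BS}/n_s + (s^2_{BD} + s^2_{\mu WD})/(n_s n_d)$
and cost $\pi_s n_s^{\alpha} + n_s \pi_d n_d^{\beta} + n_s n_d c_q$.
Throughout the package's internals, $W = s^2_{BD} + s^2_{\mu WD}$ and
$P = \pi_d + c_q$.

## How the optimizer works

Substituting the (active) budget constraint into the objective gives a
one-variable function whose minimum can sit at the interior of the choice
set (locus `I1`), at its lower or upper boundary (`E1`, `E2`), or — when
the substituted objective is concave — at whichever boundary wins the
comparison (`I2`). The dispatch is on the exponents:

* **Case A** ($\alpha = \beta = 1$): fully analytic. The optimum is
  $n_s = 1$ iff $s^2_{BS}(R-\pi_s)^2 < W P \pi_s$; it is $n_d = 1$ (with
  as many subjects as the budget buys) iff $s^2_{BS} P \ge \pi_s W$ — a
  rule that does not involve the budget at all; otherwise the interior
  solution is $n_s^\ast = R / (\pi_s + \sqrt{\pi_s P W / s^2_{BS}})$,
  $n_d^\ast = \sqrt{\pi_s W / (P\, s^2_{BS})}$, which saturates the budget
  exactly and has a budget-invariant occasion count.
* **Case B** ($\alpha = 1$, $\beta \ne 1$): the boundary condition
  $s^2_{BS}(\beta\pi_d + c_q) + W\beta\pi_d \ge W(\pi_s + \pi_d)$ settles
  the single-occasion boundary analytically; the interior requires
  enumeration. The substituted objective is provably convex for
  $\beta \ge 2$; otherwise convexity is decided numerically (below).
* **Case C** ($\beta = 1$, $\alpha \ne 1$): mirror image in $n_s$, with
  boundary condition $s^2_{BS}(R - \pi_s)^2 < W P \pi_s \alpha$.
* **Case D** (both non-linear): fully numerical.

The numerical backbone is the same in all cases: for each affordable
subject count, find the largest affordable occasion count
(`max_occasions()`, exact integer doubling-plus-bisection — never a
continuous root finder), and evaluate the objective there. Scanning only
these budget-saturating pairs is sufficient because the variance never
increases in $n_d$; when $W = 0$ occasions are worthless and the scan
short-circuits to $n_d = 1$. The closed-form Case A solution is used as a
screening device and then *integer-refined*: because the integer optimum
can sit far from the rounded continuous one (the linear worked example has
$n_s^\ast = 12.5$ but integer optimum $n_s = 13$ with a quite different
$n_d$), refinement evaluates every saturating candidate from just below
$\lfloor n_s^\ast \rfloor$ to the subject boundary. Whatever the analytic
screening says, enumeration is the authority: `optimize_design()` always
validates against it, and `method = "enumerate"` forces it outright.

### Numerical choices

* **Budget tolerance.** An allocation is feasible iff
  $c \le R(1 + 10^{-12}) + 10^{-9}$: powers with non-integer exponents are
  irrational and an exact comparison would misclassify designs that
  saturate the budget exactly in real arithmetic.
* **Tie-break.** Designs whose variances differ by less than $10^{-12}$
  (relative) count as tied; the optimizer prefers more subjects, then
  lower cost, reflecting the general supremacy of spreading measurements
  across subjects. Ties are real: with $s^2_{BS} = 0$, $\pi_s = 0$ and
  linear costs the objective depends on $n_s n_d$ only.
* **Knife edges.** Boundary conditions holding with equality are
  classified as boundary-optimal; the reference grid contains a scenario
  sitting exactly on $s^2_{BS} P = \pi_s W$ whose optimum is the boundary
  design $(22, 1)$.
* **Convexity scan.** Outside the analytic $\beta \ge 2$ regime the locus
  label uses second differences $f(n-1) - 2f(n) + f(n+1)$ with a relative
  tolerance of $10^{-9}$, so float noise is not mistaken for concavity.
  For $\beta < 2$ we check convexity numerically rather than via
  closed-form inequalities; since the optimum never depends on the label
  (enumeration decides), this affects reporting only. The same scan labels
  Case C, whose convexity we did not find worth a separate proof, and Case
  D, where no substituted one-variable objective exists and the label is
  read off the saturating profile in $n_s$.
* **Safety cap.** A scenario whose boundary search would evaluate more
  than $10^7$ candidates raises an explicit error instead of truncating
  silently. Free occasions ($\pi_d + c_q = 0$) with $W > 0$ have no finite
  optimum and are rejected with a clear message.
* **Display rounding.** Reference tables round half away from zero to two
  decimals (`round_half_away()`); full precision is kept internally and in
  CSV/JSON output.

## The reference study

`scenario_grid()` rebuilds the 225-scenario reference experiment: variance
triples $(2, 10, 10)$, $(11, 5.5, 5.5)$, $(20, 1, 1)$ — large, medium and
small between-subjects to within-subject variance ratios — crossed with
the same triples as unit costs and $\alpha, \beta \in \{0.5, 0.75, 1,
1.25, 1.5\}$ at budget 500. Both triples sum to 22, so the minimal design
$(1, 1)$ always costs 22 and always leaves variance 22; feasibility and
scale are directly comparable across scenarios. The package reproduces all
225 printed optima and two-decimal variances (the transcribed table ships
as `inst/extdata/reference_grid_optima.csv` so the comparison is
auditable), the 135 single-occasion optima at budget 500, the 139 at
budget 1000, and the 3 scenarios whose optimum moves *away* from the
single-occasion boundary as the budget grows — an integer-granularity
effect.

```{r grid, eval = FALSE}
results <- optimize_design(scenario_grid(500))
glance(results)
autoplot(results)
```

### Summary conventions, and one irreproducible endpoint

The reference summary reports a median utilization of 97.9% with a 5th–95th
percentile range of 92.3%–100.0%. With optima identical to all 225 printed
cells the utilization values are fully determined: their exact median is
97.96% and the 95th percentile rounds to 100.0%, both consistent with the
publication. The lower endpoint is not: 92.3% is the *8th* order statistic
of the 225 utilizations (the 3.6th percentile), and no standard quantile
convention (R types 1–9, over all or distinct values) places it at
$p = 0.05$ — they all give 93.5%–94.2%. `grid_summary()` therefore uses
R's default convention (type 7, linear interpolation), states it in its
output, and we report the discrepancy rather than bend the convention to
hit the printed number.

### The deviation analyses

`design_profile()` exposes the full saturating-candidate table behind the
optimizer, which is how the reference study's "what if we deviate from the optimum"
questions are answered. For variances $(2,10,10)$, costs $(20,1,1)$ and
$\alpha = \beta = 0.75$ the optimum is $(21, 9)$ with variance 0.20, and
every subject count between 15 and 32 stays within 0.23, the worst being
$(30, 4)$ — not because the design is unreasonable but because integer
granularity strands 8% of the budget. For costs $(2,10,10)$ the optimum
$(13, 2)$ (variance 0.92) is much more fragile: holding the occasion count
at its optimal value 2, every affordable subject count other than 13 and
its nearest neighbour 12 loses at least 18% (variance 1.09 or more). We
read that reference claim as a fixed-$n_d$ sweep deliberately: under the
saturating-pair enumeration used elsewhere it would be contradicted by the
study's own tables, which list e.g. $(9, 3)$ with variance 0.96 as the
optimum of a neighbouring scenario and therefore a feasible deviation here.

## The random-scenario generator

`random_scenarios()` exists for property testing, not for emulating any
particular exposure domain: variance components and unit costs are drawn
log-uniformly on $(0.1, 50)$ — the reference parameters span 1 to 20, so
this deliberately over-covers —, exponents uniformly on $(0.3, 2.5)$,
bracketing the reference $[0.5, 1.5]$ sweep, and the budget is set to the
cost of a subject-boundary design with 1–80 subjects so that every
scenario is feasible and the full feasible rectangle stays below about
$80 \times 800$ cells, small enough that an exhaustive brute-force oracle
can check the optimizer on hundreds of scenarios in seconds. Scenarios
with a deeper occasion boundary are redrawn. What passing these tests
shows is exact integer optimality under the model's assumptions; it says
nothing about misspecified variance components, non-power-law costs, or
unbalanced data, none of which the generator produces.

## Scope and limitations

* Balanced designs only: the estimator and variance algebra assume
  complete $n_s \times n_d \times n_q$ data; ragged input is rejected.
* Variance components and cost parameters are taken as known; estimating
  them (ANOVA/REML) and propagating their uncertainty into the optimal
  design are out of scope.
* $n_q$ is a fixed input, not a third optimization variable.
* The objective is the precision of a group mean. Designs optimal for
  other targets (regression slopes, exceedance probabilities, ICCs, or
  simultaneous variance-component estimation — which needs $n_d \ge 2$ and
  so conflicts with the frequent $n_d = 1$ optima) will differ.
* Costs are homogeneous power functions; empirically-shaped cost curves
  can be approximated only piecewise by re-running with local parameters.
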