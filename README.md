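# expodesign

Budget-constrained design of exposure assessment studies: how many
subjects should you recruit, and how often should you measure each one,
to get the most precise group mean exposure your money can buy?

## The problem

Exposure data (occupational, environmental, biomechanical, ...) is usually
collected through a balanced nested hierarchy — `n_s` subjects, `n_d`
measurement occasions per subject, `n_q` sampling quanta per occasion.
With variance components `(s²_BS, s²_BD, s²_q)` for between-subjects,
between-occasions and within-occasion variability, the "mean of means"
estimate of the group mean has variance

    s²_μ(n_s, n_d, n_q) = s²_BS/n_s + s²_BD/(n_s·n_d) + s²_q/(n_s·n_d·n_q)

Collecting the data costs

    c(n_s, n_d, n_q) = π_s·n_s^α + n_s·π_d·n_d^β + n_s·n_d·π_q·n_q^γ

where the `π` are unit costs and the exponents `α, β, γ > 0` allow
*non-linear* cost growth (late recruits that are harder to persuade give
`α > 1`; subjects that get used to the protocol give `β < 1`). Given the
variance components, the cost model, and a budget `R`, `expodesign`
returns the integer design `(n_s, n_d)` minimizing `s²_μ` subject to
`c ≤ R` (the quantum count `n_q` is a fixed input, folded away exactly by
`reduce_stages()`).

With linear costs the optimum has closed form; one non-linear stage leaves
analytic boundary rules plus a one-dimensional enumeration; two non-linear
stages are solved by exact enumeration of budget-saturating integer
designs. Closed forms are used for screening only — every answer is
validated against enumeration.

## Worked example

A scenario where subjects are expensive to recruit (`π_s = 20` vs
`π_d = c_q = 1`), recruitment and occasion costs both accelerate
(`α = β = 1.5`), most variability lies within subjects
(`(2, 10, 10)`), and the budget is 500:

```r
library(expodesign)

scn <- scenario_tbl(s2_bs = 2, s2_bd = 10, s2_mu_wd = 10,
                    pi_s = 20, pi_d = 1, c_q = 1,
                    alpha = 1.5, beta = 1.5, budget = 500)
tidy(optimize_design(scn))
#> # A tibble: 1 × 18
#>   s2_bs s2_bd s2_mu_wd  pi_s  pi_d   c_q alpha  beta budget   n_s   n_d variance
#>   <dbl> <dbl>    <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <int> <int>    <dbl>
#> 1     2    10       10    20     1     1   1.5   1.5    500     5    12    0.733
#>   variance_2dp  cost utilization_pct case  locus method
#>          <dbl> <dbl>           <dbl> <chr> <chr> <chr>
#> 1         0.73  491.            98.3 D     I1    enumeration
```

The optimum is 5 subjects measured on 12 occasions each: variance 0.73,
using 98.3% of the budget (integer designs rarely hit 100%). `case = "D"`
says both cost stages were non-linear, so the answer came from exact
enumeration; `locus = "I1"` says it is an interior optimum, not a boundary
design. Compare the linear-cost version of the same scenario
(`alpha = beta = 1`), whose optimum is `(13, 9)` — non-linearity alone
moved the design from 13 subjects to 5.

`design_profile(scn)` returns every budget-saturating candidate
(`autoplot()` draws it), `evaluate_design()` scores any design you are
considering, and the 225-scenario reference study is one call away:

```r
results <- optimize_design(scenario_grid(500))
glance(results)
#> # A tibble: 1 × 7
#>   budget n_scenarios median_utilization_pct p5_utilization_pct
#>    <dbl>       <int>                  <dbl>              <dbl>
#> 1    500         225                   98.0               94.2
#>   p95_utilization_pct n_single_occasion percentile_convention
#>                 <dbl>             <int> <chr>
#> 1               100.0               135 linear interpolation (quantile type 7)
```

In 135 of the 225 scenarios the best strategy is a single occasion per
subject — spreading money across subjects — but when recruitment is
expensive relative to measuring and between-subjects variance is small,
the optimum concentrates effort on few subjects and becomes very
sensitive to cost non-linearities.

A shell interface with subcommands `optimize`, `evaluate`, `table`,
`sweep` and `compare-budgets` is installed as `exec/expodesign`;
parameters come from `--key value` flags or a YAML/JSON config file.

```sh
expodesign optimize --s2_bs 2 --s2_bd 10 --s2_mu_wd 10 \
  --pi_s 20 --pi_d 1 --c_q 1 --alpha 1.5 --beta 1.5 --budget 500
```

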