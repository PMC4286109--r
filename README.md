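# swcrt

Power and minimum detectable difference for cross-sectional
stepped-wedge and parallel cluster randomised trials, driven by a
**design pattern matrix** — a clusters × periods grid in which every cell
is control (`0`), exposed to the intervention (`1`), or unobserved (`.`).
One grid language covers the complete stepped wedge, incomplete wedges
with transition (implementation) periods, staggered-but-parallel designs,
before/after parallel trials with baseline measures, and designs with two
nested levels of clustering (wards within hospitals, hospitals within
regions).

The package is for trial statisticians and methodologists designing
cluster trials: it answers "what power does *this* schedule give?" for
schedules that the classical design-effect formulas cannot represent.

## The method

Observed cell means (the mean outcome of the `m` individuals in one
cluster-period cell) follow the linear mixed model

    y_cell = θ_t + δ·J_jt + α_j (+ β_jl) + noise,

with fixed period effects θ_t, intervention effect δ, exposure indicator
J_jt, random cluster effects α_j ~ N(0, τ²) and — with a second
clustering level — random group effects β_jl ~ N(0, b²).  With variance
components treated as known, the cell means are multivariate normal with
mean Xβ and block-diagonal covariance V (one compound-symmetric block per
cluster, shrunk by deleting rows/columns for unobserved cells).  The GLS
variance of the treatment effect is

    Var(δ̂) = [(X′ V⁻¹ X)⁻¹]₁,₁

and the two-sided Wald power at level α is

    1 − β = Φ( |δ| / √Var(δ̂) − z_{α/2} ).

Closed-form routes are provided where they exist — the parallel-CRT
design effect `1 + (m−1)ρ`, and the baseline-adjusted (ANCOVA-style)
design effect `2[1 + (m−1)ρ](1 − r²)` with cluster-mean correlation
`r = mρ / (1 + (m−1)ρ)` — and agree with the matrix route to 1e-10,
which the test suite verifies.  A seeded Monte-Carlo simulator
(`simulate_cell_means()`, `gls_estimate()`, `empirical_power()`)
cross-checks every analytic number empirically.

## A worked example

A complete stepped wedge with 4 clusters, 5 periods and 25 observations
per cell, ICC 0.05, looking for an effect of 0.3 SD:

```r
library(swcrt)
d <- complete_sw(4, 1, cell_size = 25)
d
#> complete design pattern: 4 clusters x 5 periods (500 observations)
#>          p1 p2 p3 p4 p5
#> cluster1 0  1  1  1  1
#> cluster2 0  0  1  1  1
#> cluster3 0  0  0  1  1
#> cluster4 0  0  0  0  1

sw_power(d, one_level_from_icc(0.05, 1), effect_spec(delta = 0.3, sd = 1))
#> Var(delta_hat) = 0.0232851  (SE 0.152595)
#> power          = 0.5024  (delta 0.3, two-sided alpha 0.05)
#> delta_min      = 0.427507  (at power 0.8)
```

So this schedule detects δ = 0.3 with only 50% power; the smallest effect
detectable at 80% power is 0.43.

A parallel trial with baseline measures shows the characteristic
*non-monotone* power-vs-ICC profile (rising ICC hurts through the design
effect but helps through the baseline correlation `r`):

```r
nursery_power_table()
#>    icc         r     power power_ancova
#> 1 0.05 0.4411765 0.8909580    0.8909580
#> 2 0.10 0.6250000 0.8703536    0.8703536
#> 3 0.15 0.7258065 0.8693645    0.8693645
#> 4 0.20 0.7894737 0.8772270    0.8772270
#> 5 0.30 0.8653846 0.9045872    0.9045872
#> 6 0.40 0.9090909 0.9369114    0.9369114
#> 7 0.50 0.9375000 0.9666925    0.9666925
```

Both computation routes (information matrix vs. baseline-adjusted design
effect) are shown and are identical; the minimum sits at ICC 0.15.

## Command line

A thin `swcrt` executable (installed under `exec/`) wraps the same
functions:

    swcrt design --kind complete --steps 4 --cell-size 25 -o design.csv
    swcrt power  --design design.csv --cell-size 25 --icc 0.05 \
                 --delta 0.3 --sd 1 --format json
    swcrt examples table1

Flags can come from a YAML file via `--config run.yaml` (explicit flags
override it), and `--format json` emits machine-readable output.

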