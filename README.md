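# cgtree: survival trees and two-sample tests under dependent censoring

Kaplan–Meier curves, the logrank test and the survival trees built on them
all assume that censoring is independent of the event process. In many
clinical settings that assumption is wrong in a consequential way: patients
who drop out because of adverse events or lack of improvement tend to have
shorter residual survival than those who stay, so independence-based
estimates are biased — optimistically so under positive dependence.

`cgtree` provides inference and recursive partitioning for right-censored
data that let the analyst *specify* the dependence between event time `T`
and censoring time `C` instead of assuming it away. It is aimed at
biostatisticians analysing clinical-trial or registry survival data with
suspected informative dropout, and at methodologists studying such
procedures by simulation.

## The model and statistic

Dependence is modelled by an Archimedean copula on the joint survival
function, `P(T > t, C > s) = φ⁻¹(φ(S_T(t)) + φ(S_C(s)))`, with the Clayton
family (generator `φ(u) = (u^−θ − 1)/θ`, Kendall's `τ = θ/(θ+2)`), the
Frank family, and independence (`φ(u) = −log u`) built in. Under an assumed
copula, the survival function is estimated by the **copula-graphic
estimator (CGE)** — a step function that generalises Kaplan–Meier (it
reduces to it exactly at `τ = 0`) while remaining consistent under the
specified dependence.

Two groups are compared with the time-normalised integrated absolute
CGE distance

    L1 = (1 / t*) ∫₀^t* | Ŝ₁(t) − Ŝ₂(t) | dt,   t* = min(max x₁, max x₂),

whose null distribution is obtained by a **permutation test**: group labels
of the pooled `(time, status)` pairs are re-randomised with group sizes
fixed (valid under equal censoring distributions, which make the pairs
exchangeable under H0). The signed variant of `L1` orders the groups by
prognosis. A **survival tree** (`cg_tree()`) uses the permutation p-value as
its splitting criterion: each node grid-searches all covariate/cutoff
candidates, splits while the minimal p-value is at or below a threshold
`p̃`, sends the better-prognosis child to the right, and numbers terminal
nodes right-to-left so node 1 always has the best prognosis. A
logrank-split comparator tree runs on the same engine
(`split_test = "logrank"`).

The package also ships the simulation machinery around the method:
proportional-hazards and Gompertz non-proportional-hazards generators with
copula-dependent censoring calibrated so a fraction `r` is censored under
the null, a block-correlated "pathway" covariate generator, evaluation
metrics (selection precision, Harrell's C on terminal-node ranks,
censoring-weighted integrated Brier score), and a harness for type-I-error
and power studies.

## Worked example

Simulate two groups of 60 with strongly different survival
(`beta = -1.2`), 50%-calibrated censoring and Clayton-dependent censoring
(`τ = 0.5`), then test and grow a tree under the correctly specified
copula:

```r
library(cgtree)

dat <- simulate_ph(n1 = 60, n2 = 60, beta = -1.2, r = 0.5,
                   copula = make_copula("clayton", 0.5), seed = 7)
res <- permutation_test(as_two_sample(dat), make_copula("clayton", 0.5),
                        nperm = 1000, seed = 42)
res
#> Two-sample CGE permutation test
#> Archimedean copula: clayton (theta = 2, Kendall tau = 0.5)
#> L1 = 0.747667, signed L1 = -0.747667
#> p-value = 0.001 (Monte-Carlo, 1000 permutations)

tree <- cg_tree(dat[c("time", "event", "z")], make_copula("clayton", 0.5),
                p_threshold = 0.01, nperm = 500, seed = 11)
tree
#> Survival tree (cge splits, clayton copula, tau = 0.5), n = 120, 2 terminal node(s)
#>  split z <= 0 (p = 0.002)
#>   [L] leaf #2: n = 60, median = 0.7985
#>   [R] leaf #1: n = 60, median = NA
```

The average gap between the two CGE curves over the common observation
window is about 0.75 survival-probability units; none of the 999 random
relabelings reached it, so `p = 1/1000`. The negative signed L1 says group 2
survives longer; accordingly the tree's first (and only) split puts the
`z = 0` subjects in leaf 2 and the longer-surviving `z = 1` subjects in
leaf 1, whose median survival is not reached (`NA`).

Choosing the assumed `τ` is the analyst's burden: `cv_select_tau()` grows
trees over a τ grid under event-stratified cross-validation and reports
mean tree size, Harrell's C and integrated Brier score per τ. A thin CLI
(`inst/cli/cgtree.R`) exposes `test`, `tree`, `cv-tau`, `simulate` and
`study` subcommands for CSV survival tables.

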