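# rpindex

Revealed-preference inconsistency indices for linear budget-set choice
experiments.

## The problem

In graphical budget-line experiments a subject repeatedly allocates tokens
between two accounts along a randomized linear budget line (each point is a
50/50 lottery over the two accounts).  A consistent subject — one
maximizing some well-behaved utility — must satisfy the Generalized Axiom
of Revealed Preference (GARP): no chain of revealed preferences may
contradict a strict direct revealed preference.  Real subjects violate
GARP, and the interesting question is *by how much* and *on which trials*.
`rpindex` is for experimental economists and decision neuroscientists who
need, from a session of such choices:

* nonparametric aggregate indices — the GARP violation count and the
  Afriat critical-cost-efficiency index `1 − e*`, where `e*` is the
  largest uniform budget deflation under which the deflated data satisfy
  GARP;
* the parametric **Money Metric Index (MMI)**: for a utility *u* the money
  metric `m(xⁱ, pⁱ, u) = min { pⁱ·y : u(y) ≥ u(xⁱ) }` is the cheapest
  expenditure still affording something as good as the chosen bundle, the
  per-trial adjustment is `vᵢ* = 1 − m/(pⁱ·xⁱ)`, and the index minimizes
  `sqrt(mean(v*²))` over a disappointment-aversion utility family
  (`SV(x,y) = γ ω(max) + (1−γ) ω(min)`, `γ = 1/(2+β)`, with CRRA or CARA
  curvature ω), returning the best-fitting parameters as a by-product;
* the **trial-specific inconsistency index**: a leave-one-out difference
  `ε(D) − ε(D₋ᵢ)` scoring the severity of inconsistency each single choice
  contributes — usable as a per-trial regressor;
* a **choice-simplicity** (difficulty) score for continuous budget sets
  and the per-trial regressor table (RT, trial MMI, subjective value, log
  price ratio, endowment, simplicity, a confidence proxy);
* a **neural random utility (NRUM) simulator**: skewed valuation noise
  (zero-mode Gumbel or zero-mean lognormal) added to every bundle's value,
  noise-scale calibration to a target Afriat level, and the pooled
  noise-vs-inconsistency correlation diagnostic that links valuation noise
  to inconsistent choice;
* a synthetic task generator (randomized budget lines, standard chooser
  strategies) so everything above is testable without any experimental
  data.

## Worked example

```r
library(rpindex)

# a simulated random chooser on 108 randomized budget lines
rand <- simulate_subject(108, "uniform_random", seed = 42)
garp_violations(rand)
#> GARP at e = 1: violated (4507 violating ordered pairs)
afriat_index(rand)
#> [1] 0.6932678
aggregate_mmi(rand)
#> aggregate MMI = 0.24963 (DA_CRRA)
#> DA-CRRA utility: beta = -0.2145 (gamma = 0.5601), rho = 0.642

# a noiseless utility maximizer is consistent and exactly recoverable
truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
cons <- simulate_subject(108, "maximize", seed = 42, params = truth)
garp_violations(cons)$n_violations
#> [1] 0
aggregate_mmi(cons)
#> aggregate MMI = 1.43e-14 (DA_CRRA)
#> DA-CRRA utility: beta = 0.5 (gamma = 0.4), rho = 0.5

# which trials carry the inconsistency?
loo_index(rand, "afriat")
#> trial-specific afriat index: n = 108, aggregate = 0.69325
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.000000 0.000000 0.000000 0.005368 0.000000 0.289881
```

The random chooser racks up thousands of violating ordered pairs and an
Afriat index near 0.7 — budgets would have to be deflated ~70% before its
choices look rationalizable — while the maximizer scores zero on every
index and its generating parameters are recovered to three decimals.
`loo_index(ds, "mmi")` gives the parametric trial-specific series, which
varies across nearly all trials rather than being mostly zero.

A thin command-line front end over the same functions is installed at
`inst/cli/rpindex.R` (subcommands `simulate`, `indices`, `mmi`, `loo`,
`simplicity`, `regressors`, `nrum`, `nrum-demo`).

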