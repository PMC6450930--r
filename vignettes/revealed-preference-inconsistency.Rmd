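---
title: "Measuring choice inconsistency on linear budget sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring choice inconsistency on linear budget sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpindex)
```

## The task and the data

`rpindex` analyzes choice data from the graphical budget-line task widely
used to test consistency with utility maximization under risk.  On each
trial a subject allocates tokens between two accounts X and Y along a
linear budget line; one account is later paid with probability 1/2, so each
point on the line is a 50/50 lottery.  Axes run 0–100 tokens at 0.1-token
resolution, and slopes and endowments vary across trials.  A session is a
`choice_dataset`: per trial, two prices, an expenditure, the chosen bundle
$(x, y)$ on the line, and optionally a response time.

Prices and expenditure are only identified up to a per-trial scale, so the
package normalizes internally to expenditure 1 (`price_x` = 1/x-intercept,
`price_y` = 1/y-intercept).  Every index below is invariant to that
normalization, and the test suite asserts the invariance.

## Nonparametric indices: GARP, violation counts, the Afriat index

Bundle $x^i$ is *directly revealed preferred* to $x$ if $p^i x^i \ge p^i x$
($R^0$; strictly, $P^0$), and *revealed preferred* ($R$) through the
transitive closure of $R^0$.  The data satisfy GARP when no ordered pair
has $x^i R x^j$ together with $x^j P^0 x^i$.  `garp_violations()` counts
violating *ordered pairs* (a mutual strict 2-cycle counts as 2); this is
the counting convention under which random-chooser benchmarks on 108-trial
sessions land in the thousands out of $108 \times 107$ ordered pairs.

The Afriat critical-cost-efficiency index is $1 - e^*$, where $e^*$ is the
supremal efficiency level at which the $e$-deflated data ($e \cdot p^i x^i
\ge p^i x$ in place of $R^0$, strict for $P^0$) satisfy GARP.  Deflating
budgets only shrinks the relations, so GARP($e$) is monotone in $e$ and
`afriat_index()` bisects on $[0, 1]$ to a tolerance of $10^{-4}$
(midpoint of the final bracket reported; exactly 0 for consistent data).
The package also ships an exact method: with the cost-ratio matrix
$W_{ij} = p^i x^j / p^i x^i$ and its minimax-path closure $B$ (the
smallest possible "largest affordability ratio" along any preference
chain), $e^* = \min_{i \ne j} \max(B_{ij}, W_{ji})$ capped at 1.  The two
methods agree to the bisection tolerance; leave-one-out and simulation
internals use the exact form because differences of exact $e^*$ values are
themselves exact (in particular, nonnegative).

## The parametric Money Metric Index

Counting violations throws away magnitudes.  The Money Metric Index (MMI)
instead asks: how much expenditure adjustment would reconcile the choices
with the *best-fitting* utility in a parametric family?  For a utility $u$
and observation $i$, the money metric

$$m(x^i, p^i, u) = \min_{u(y) \ge u(x^i)} p^i y$$

is the cheapest expenditure at prices $p^i$ that still affords something
as good as the chosen bundle; the normalized adjustment is
$v^*_i = 1 - m / (p^i x^i) \in [0, 1)$.  `aggregate_mmi()` minimizes the
root of the average squared adjustment,
$\sqrt{\tfrac1n \sum_i v_i^{*2}}$, over the family's parameter box and
reports the minimum, the recovered parameters, and the per-trial
adjustments at the optimum.  The root-mean-square aggregator keeps the
index on the same fraction-of-expenditure scale as the Afriat index
(`aggregator = "mean_sq"` gives the raw average of squares; the two are
monotone transforms, so the recovered parameters are identical).

### The utility family

The family is disappointment aversion over 50/50 lotteries:

$$SV(x, y) = \gamma\, \omega(\max\{x,y\}) + (1-\gamma)\, \omega(\min\{x,y\}),
  \qquad \gamma = \frac{1}{2+\beta},\; \beta \ge -1,$$

with CRRA curvature $\omega(z) = z^{1-\rho}/(1-\rho)$ ($\ln z$ at $\rho =
1$) or, as a robustness family, CARA curvature $\omega(z) = 1 -
e^{-Az}$.  $\beta = 0$ is expected utility, $\beta > 0$ overweights the
worse outcome, $\beta < 0$ ("elation seeking") the better one; $\beta =
-1$ cares only about the larger amount and $\beta \to \infty$ approaches
the safe-bundle (max–min) limit.  CRRA with $\rho \ge 1$ is undefined at
0 tokens; amounts are floored at $10^{-6}$ tokens there, which matters
only for corner bundles.

Estimation boxes: $\beta \in [-1, 10]$ and $\rho \in [0, 10]$ — beyond 10
the implied behavior is indistinguishable from corner/max–min choices at
0.1-token resolution — and $A \in (0, 1]$ for CARA (with token amounts up
to 100, $A = 1$ is already effectively max–min; the grid is log-spaced
from $10^{-3}$).  The coarse grid (default about 21 points per axis)
always contains the special points $\beta \in \{-1, 0\}$ and $\rho \in
\{0, 1\}$, so expected value, expected utility, and Cobb–Douglas are
always candidates.  Nelder–Mead refinement starts from the best grid
cells with parameters clamped to the box; there are no stochastic
restarts, so the whole pipeline is bit-reproducible.

### Money-metric numerics

$SV$ depends on the bundle only through its larger and smaller
coordinate, so the level set through $x^i$ splits at the 45° line into
two smooth branches.  On the branch where the first coordinate is the
larger one, the boundary solves $y(x) = \omega^{-1}\!\big((u_0 - \gamma\,
\omega(x)) / (1-\gamma)\big)$, with $\omega^{-1}$ available in closed form
for both families ($\omega^{-1}(t)$ is implemented as the smallest
$z \ge 0$ with $\omega(z) \ge t$, $+\infty$ when $t$ exceeds the range
supremum, so out-of-range levels degrade gracefully).  The solver
evaluates, per trial: the chosen bundle itself (so $m \le p^i x^i$ holds
exactly), the 45° kink bundle, both axis corners, and a scanned grid on
each branch with three passes of local refinement.  Corners are always
evaluated explicitly because for $\beta < 0$ the preferred set is
non-convex and the minimum can jump there; at $\beta = -1$ the minimum
*is* one of the corners.  The unit tests compare against a dense-scan
oracle (20,000-point grid with a 60-step bisection per point) across
random parameters including the non-convex range, at relative tolerance
$2\times 10^{-3}$.

### The leave-one-out trial-specific index

For any aggregate index $\varepsilon$, the trial-specific value of
observation $i$ is $\varepsilon(D) - \varepsilon(D_{-i})$: the
inconsistency the trial contributes.  `loo_index()` supports the
parametric MMI (utility parameters re-estimated for every $D_{-i}$, since
the definition minimizes per dataset) and the nonparametric Afriat and
violation-count indices.  Removing an observation can only shrink the
revealed-preference relations, so the nonparametric series are
nonnegative; the MMI series can be mildly negative for
consistency-anchoring trials because the mean-of-squares denominator
shrinks when a trial is removed.  The $D_{-i}$ optimizations warm-start
at the full-data optimum plus a reduced grid and a short refinement — an
approximation knob; `exact = TRUE` re-runs the full search per trial.
The trial-specific MMI is the package's main product for trial-level
analysis: unlike the nonparametric variants, which are mostly zero, it
varies across nearly every trial, which is what makes it usable as a
per-trial regressor.

## The synthetic task generator

`generate_budgets()` emulates the experimental geometry: both intercepts
drawn uniformly on the 0.1-token grid in $[1, 100]$, redrawn until the
larger intercept is at least 50.  The exact sampling law used in the
original task family is not published; this law reproduces the documented
"substantial variation of slopes and endowments" with both steep and
shallow lines, and both bounds are exposed as parameters.  Note the
redraw rule constrains only the *larger* intercept, so degenerate bounds
(`min_major_intercept = max_intercept = 100`) pin one intercept at 100
and leave the other free.  Chooser strategies cover the behaviors such
experiments discuss: uniform-random over the discretized line (the
benchmark "random decision-maker"), the safe 45° bundle, the
cheaper-corner heuristic, equal expenditure split (Cobb–Douglas
behavior), exact utility maximization (which provably satisfies GARP and
anchors the zero points of all indices), and random-utility choice (next
section).  One integer seed drives a session; budget and choice draws
consume distinct per-trial substreams, so trial $k$ is reproducible
independently of the number of trials requested.

What the generator does *not* emulate: response-time generation, motor or
numerical imprecision in executing a choice, payment mechanics, or
block-structured preference changes.  Passing tests on synthetic data
therefore show that the indices behave correctly on data with the task's
geometry and the modeled choice processes — not that any particular human
population will exhibit a given index distribution.

## The neural random utility simulator

The NRUM treats the valuation of every candidate bundle as stochastic:
$\tilde v_b = v_b + e_b$, with $v_b$ the subjective value under the
subject's utility and one independent skewed noise draw $e_b$ per bundle
on the 0.1-token grid; the chosen bundle maximizes $\tilde v$.  Two
one-parameter right-skewed families are implemented: a zero-mode Gumbel
(location 0, scale $s$) and a zero-mean shifted lognormal ($e^{sZ} -
e^{s^2/2}$, $Z \sim N(0,1)$).  Because the noise is skewed, choosing a
clearly dominated bundle requires a large positive realization — so the
model predicts that the valuation signal is *elevated*, not depressed, on
inconsistent trials.

`calibrate_noise()` picks the scale so the mean Afriat index over
simulated sessions matches a target (how a simulated subject is matched
to an observed inconsistency level): the mean Afriat level is monotone in
the scale, so a bisection with common random numbers converges quickly;
the default is 50 repetitions per scale evaluation with a ±10% relative
stopping rule.  `nrum_assess()` then simulates many sessions, computes
each trial's leave-one-out Afriat value — the nonparametric stand-in for
the trial-specific MMI, avoiding re-use of the fitted utility — and
pools the chosen-bundle noise against the trial-specific Afriat values
across trials × repetitions.  Under the model the pooled correlation is
positive and extremely significant at 1000 repetitions, and shuffling
the noise across trials destroys it; both are asserted in the tests for
both noise families.

`conditional_utility_demo()` is the discrete-alternative illustration.
Two parameterizations are provided because the random-utility story can
be told multiplicatively or additively, and the two make different
fine-grained predictions.  With *multiplicative* noise (lognormal draws
whose arithmetic mean equals the alternative's valuation, common log-sd)
the choice probability of the worse of two alternatives has the closed
form $\Phi(-\log(m_1/m_2) / (\sigma\sqrt2))$ — about 0.242 for
valuations 4 vs 2 at $\sigma = 0.7$ — and the inconsistent alternative's
conditional mean utility exceeds its valuation, by more when the
valuation gap widens.  With *additive* zero-mean lognormal noise (the
same family the dataset simulator uses) every alternative faces the same
skewed shock, so the conditional mean of the chosen utility *rises* as
worse alternatives are chosen — the severity gradient.  Under the
multiplicative variant that gradient runs the other way (worse
alternatives have proportionally smaller spreads), which is why both
variants are exposed rather than one blended compromise.

## Choice difficulty and the regressor table

`choice_simplicity()` scores how easy a budget line is for a given
utility: discretize the line into $N$ bundles (default 1000, uniform in
$x$, corners included), compute each bundle's subjective value $v_i$, and
return $(\max_i v_i - \operatorname{mean}_i v_i) / \text{Endowment}$.
Near 0 means the line is nearly value-flat — a difficult choice.  The
endowment divisor removes over-scoring of longer lines; it is the
safe-portfolio token count $m/(p_x + p_y)$ by default, matching the
endowment regressor, with raw expenditure exposed as an option because
the normalization unit is a genuine modeling choice (the two differ
trial-by-trial by the factor $p_x + p_y$).

`regressor_table()` assembles the per-trial design matrix for downstream
regressions (e.g., of a neural or behavioral signal on inconsistency):
response time, trial-specific MMI, subjective value of the chosen bundle
at the recovered parameters, log price ratio, endowment, simplicity, and
a confidence proxy (squared subjective value, the second-order term of a
polynomial in SV).  Fitting such regressions is left to standard tools.

On simulated random-utility subjects at realistic inconsistency levels,
simplicity explains very little of the trial-specific MMI variance
($R^2$ well under 0.1, which the tests assert on a pooled five-subject
run).  The *sign* of that weak association is not stable across
simulated subjects: ranking flips are more frequent on difficult
(value-flat) trials, but each flip there costs little expenditure
adjustment, and which force wins varies with the noise scale and seed.
A reliably negative sign in empirical data is therefore a behavioral
finding about real choosers, not something this simulator guarantees.

## A worked example

```{r example, eval = FALSE}
truth <- utility_params("DA_CRRA", beta = 0.5, rho = 0.5)
ds <- simulate_subject(108, "maximize", seed = 42, params = truth)
garp_violations(ds)$n_violations   # 0: maximizers satisfy GARP
afriat_index(ds)                   # 0

rand <- simulate_subject(108, "uniform_random", seed = 42)
garp_violations(rand)$n_violations # thousands of ordered pairs
afriat_index(rand)                 # ~0.5
fit <- aggregate_mmi(rand)         # ~0.23 with recovered parameters
loo <- loo_index(rand, "afriat")   # per-trial inconsistency shares
```

## Problem sizes, tolerances, and other numerical choices

* Budget-line residual tolerance `tol_budget` = $10^{-6}$ of expenditure
  (after normalization); rows further off the line are dropped on read
  with a per-row report, mirroring the exclusion of no-choice trials from
  a session.
* Afriat bisection tolerance $10^{-4}$; revealed-preference inequalities
  use exact $\ge$ / $>$ with no epsilon slack (grid coordinates are exact
  decimals; prices are normalized first).
* `optimal_bundle()` ties are broken toward larger $x$; refinement uses
  golden-section search at tolerance $10^{-9}$ on the bracket around the
  best grid point, with the exact safe bundle and corners always included
  as candidates.
* The distribution-level acceptance checks in the test suite use 500
  simulated random choosers for violation counts, 300 for the Afriat
  median, and 50 for the MMI median (the published benchmark used
  25,000); parameter recovery uses 20 sessions of 108 trials; the NRUM
  diagnostic uses 1000 repetitions per noise family.  These sizes give
  median sampling errors well inside the tolerances asserted and are the
  package's chosen desk-scale defaults.

## Known limitations

* Varian and Houtman–Maks indices are not implemented (their exact
  computation is combinatorial and infeasible at 108 observations), so
  the leave-one-out engine offers MMI, Afriat, and violation counts only.
* The MMI is parametric: its value includes a misspecification component
  on top of pure inconsistency.  The CARA family is provided to check
  robustness to the curvature family (on CRRA-generated data the CRRA fit
  is never worse, which the tests assert).
* The budget sampling law is an informed reconstruction, exposed through
  parameters; distribution-level benchmark comparisons inherit that
  assumption.
* With 2-good linear budgets, mutual non-comparability and the precise
  counting convention (ordered pairs) matter for the magnitude of
  violation counts; comparisons with other implementations should check
  conventions first.
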