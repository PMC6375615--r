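---
title: "Methods: stochastic DEA with fuzzy expert interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic DEA with fuzzy expert interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtesim)
```

## The problem and the model

A regional mental-health system is observed as a rectangular matrix of
non-negative rates per 100,000 inhabitants: one row per small health
area (the decision-making unit, DMU), one column per indicator.
Indicators split into *provision* inputs — availability of care teams
(`T`), placement capacity (`P`), workforce capacity (`Prof`) — and
*utilisation* outputs (`U`), across residential (`R`), day (`D`) and
outpatient (`O`) types of care. The default analysis shape is 19 areas
by 57 indicators (43 inputs, 14 outputs).

The package answers three questions about such a system:

1. **How efficient is each area**, relative to the best practice
   observable among its peers, from several analyst-defined points of
   view (scenarios)?
2. **How certain and how stable** is that assessment when the data are
   perturbed within realistic bounds?
3. **What changes** when resources are shifted between areas?

### Relative technical efficiency

Efficiency is scored by data envelopment analysis under variable
returns to scale (the convexity constraint $\mathbf 1^\top\lambda = 1$
on the peer weights), which does not force output to scale
proportionally with input — the realistic assumption for health
services. For DMU $k$ with input matrix $X$ and output matrix $Y$:

* input orientation: $\min\theta$ subject to
  $X^\top\lambda \le \theta x_k$, $Y^\top\lambda \ge y_k$,
  $\mathbf 1^\top\lambda = 1$, $\lambda\ge 0$;
* output orientation: $\max\varphi$ subject to
  $X^\top\lambda \le x_k$, $Y^\top\lambda \ge \varphi y_k$,
  $\mathbf 1^\top\lambda = 1$, $\lambda\ge 0$.

A second phase fixes the radial factor and maximises total slack
(lexicographic tie-break: radial factor first, then slack). Scores are
reported on a common $[0,1]$ scale: $\theta$ directly, and $1/\varphi$
for the output orientation, so summaries of either orientation are
comparable; the raw $\varphi$ is retained in the result object. A DMU
is *efficient* when its score is 1 and total slack is zero within
tolerance, *weakly efficient* when the score is 1 but slack remains,
*inefficient* otherwise.

The envelopment (not multiplier) form is solved because the slacks are
needed for the weak/full efficiency distinction. The solver is a dense
two-phase primal simplex in compiled code; the test suite checks it
against an independently coded multiplier-form (dual) program on small
instances, where the two must agree by LP duality.

### Monte-Carlo randomization

Structural uncertainty is injected by replacing each observed value
$x$ with a distribution: triangular $T[w_{tl}x,\ x,\ w_{tr}x]$ with
defaults $w_{tl} = 0.9$, $w_{tr} = 1.1$ (the observed value is the
mode of a ±10 % relative band), or uniform $U[x,\ w_{ur}x]$,
$w_{ur} = 1.1$, for cells an analyst designates (typically indicators
believed to be under-recorded, where the observed value is a floor
rather than a midpoint). Zero cells have no relative band and stay
degenerate, as does everything when the weights are 1. Which cells are
uniform or exempt is configuration, defaulting to none.

Each simulation draws the *whole* matrix — the frontier is
simulation-wide, so all DMUs must be sampled jointly before any LP is
solved. Triangular sampling uses the inverse-CDF transform of a single
uniform draw, making runs bit-reproducible across platforms given the
seed.

### Fuzzy interpretation

Expert knowledge enters as an interpretation layer between sampling and
scoring. Each linguistic variable carries five normal fuzzy sets
(*very little, little, standard, much, very much*): linear shoulders at
the extremes, triangles inside, peaks evenly spaced. This geometry
gives, by construction, a partition of unity with at most two active
sets at any point. Defuzzification is the product-sum gravity method,
$\hat x = \sum_k m_k c_k A_k / \sum_k m_k A_k$ with per-set centroids
$c_k$ and areas $A_k$.

Day-care ($D$) and outpatient ($O$) provision are summarised per DMU
into scores on $[0,100]$: the min–max-normalised group mean of the
provision variables is fuzzified on the unit partition and projected
onto the score scale. One design choice matters here: a shoulder set's
centroid is interior to the universe, so gravity defuzzification over
shoulder-extreme sets can never reach 0 or 100 — yet the construct
scale is anchored at "no availability" = 0 and "maximum" = 100. The
construct *output* partition therefore uses symmetric equal-area
triangles centred on the peaks, which makes the gravity method
interpolate the peaks exactly: the score is linear in the group mean,
bounded, monotone in every contributing variable, and attains its
anchors. Input-side partitions keep the shoulder geometry.

Residential care is modelled as *dependent* on day and outpatient
provision: rules of the form "IF O is very little AND D is little THEN
the left appropriateness bound is much" displace the interpretation
range of each residential variable. The shipped default rule base is
the monotone 5×5 table with consequent index
$6 - \lceil (a+b)/2 \rceil$ for antecedent label indices $a$ (D) and
$b$ (O) — scarcer day/outpatient provision pushes the residential
appropriateness floor up — and is fully replaceable in the
configuration. Rule firing uses product inference and sum aggregation;
the defuzzified consequent over the variable's expert `left_universe`
becomes the new left bound, and the right bound follows at the exact
original width, $x^{right\prime} = x^{left\prime} + (x^{right} -
x^{left})$.

Finally each sampled value is mapped through a piecewise-linear
profile relative to its range. Two non-trivial profiles ship:

* `"centred_literal"`: $x^{int} = (x^{right} - x^{left}) - x$. This is
  the printed form of the reference transform; note that for ranges
  much narrower than the value itself it is negative (for a range
  (0.9753, 1.0979) and $x = 0.9753$ it yields $-0.8527$).
* `"centre_distance"`: $x^{int} = |x - (x^{left}+x^{right})/2|$, a
  tent-shaped distance from the range centre — zero at the most
  appropriate value, growing linearly with deviation either way.

The stated intent ("the more centred the value the more appropriate")
matches the tent reading, while the printed formula is the literal
one; both are provided and neither is asserted as canonical. The
default configuration uses `"centre_distance"` for residential inputs
because a non-negative "misfit" quantity behaves like a resource in
input-oriented DEA; the literal profile is selectable per variable.

The default configuration derives appropriateness ranges from the data
(±10 % around each column median, left universe $[0,\max]$, construct
universes $[0, 1.25\max]$). These are stand-ins for expert
elicitation: real studies should supply a hand-written configuration,
for which the YAML schema in `write_fuzzy_config()` is the interface.

### Distribution indicators

Each pooled score distribution is binned into `inttot = 22` intervals:
twenty half-open score bins $[0,0.05),\dots,[0.95,1)$, then the weakly
efficient bin, then the fully efficient bin. On the frequencies
$freq_h$:

* interval stability: $100 - 100\,(nint-1)/(inttot-1)$ with $nint$ the
  number of populated intervals;
* density stability: accumulate frequencies in descending order until
  the running sum first strictly exceeds `prob` (default 0.8); with
  $acprob$ that sum over $nintprob$ intervals,
  $100\,[\ln(100\,acprob/nintprob) - minln]/(maxln - minln)$;
* weighted stability: $w_{int}\,intstab + w_{den}\,denstab$ (defaults
  0.5/0.5);
* Shannon entropy $-\sum freq_h \log_2 freq_h$ and its percentage of
  $\log_2 inttot$.

The default anchors `minln = 1.2909`, `maxln = 4.6051` are the
conventional printed constants; they equal $\ln(100\,prob/inttot)$ and
$\ln 100$ to four decimals, and `stability_params(derive_ln = TRUE)`
recomputes them from `prob` and `inttot` for non-default binnings.
Because the printed `maxln` is truncated below $\ln 100$, the
all-mass-in-one-interval case evaluates to 100.002; the indicator is
defined on $[0,100]$, so the implementation clamps there. Ties between
equally frequent intervals during accumulation resolve toward the
higher-efficiency interval; the indicator depends on frequencies only,
so this affects reporting of `nintprob` order, never the value.

The "efficiency error" statistic is reported as
`error_factor × sd` with default factor 1. Published tables in this
tradition show an error column at a constant ≈1.24 multiple of the
standard deviation without a printed definition; rather than bake in
an unexplained constant, the multiple is left to the user.

### Interventions and comparison

An intervention is an explicit list of cell edits — DMU, variable,
signed change — optionally in head-count units converted to rates with
each area's population. No secondary effects are inferred: if a
restructured service serves several areas, each affected cell must be
listed. The edited dataset gets a freshly built randomization plan, so
the ±10 % bands re-centre on the post-intervention values.

Pre/post pools (computed with identical seeds and configuration apart
from the edit) are compared by: Welch/Student two-sample t-test
(Student unless Levene rejects variance equality at 0.05), the classic
mean-centred Levene test (one-way ANOVA on absolute deviations), and
the two-sample Kolmogorov–Smirnov test, each reported at α = 0.05 and
0.01, alongside Pre / Post / Variation (%) tables of all estimators
and stability indicators. For degenerate pools (an always-efficient
DMU has zero score variance) the t statistic is undefined and is
reported as `NA` with no rejection.

## Numerical choices

* **LP tolerances.** Pivot tolerance 1e-9; efficiency boundary 1e-6
  (both on scores in $[0,1]$ and scaled slacks). Dantzig pricing with
  an automatic restart under Bland's rule (smallest-index entering,
  smallest-basis-index leaving among ties) if the iteration cap is
  hit, which guarantees termination on degenerate instances.
* **Column scaling.** DEA scores are invariant to per-column
  rescaling; every input and output column is normalised to unit
  maximum before the simplex runs, and per-variable slacks are
  reported back in original units. `slack_total` is kept on the scaled
  axes as a scale-free gauge of the efficient/weakly-efficient
  boundary. Without this, instances mixing utilisation rates of order
  500 with near-zero interpreted inputs are numerically
  ill-conditioned.
* **Near-zero inputs.** Interpreted inputs can be 0 (a perfectly
  centred value under the tent profile). Raw inputs are floored at
  `input_floor` (default 1e-9) and scaled columns are clamped at a
  1e-7 relative floor, far below any data resolution but safely above
  the pivot tolerance.
* **Score snapping.** Radial objectives within 1e-6 of 1 are recorded
  as exactly 1, so pool semantics (`class != "inefficient"` implies
  `rte == 1`) hold exactly.
* **Width preservation** in range displacement is exact by
  construction ($x^{right\prime}$ is computed as
  $x^{left\prime} + width$); tests assert it at 1e-14, the resolution
  of IEEE double subtraction.
* **Seeding.** One root seed spawns one substream seed per
  (simulation, scenario) via `sample.int` on R's Mersenne–Twister.
  Runs are reproducible record-for-record, and both orientations are
  solved on the same realization so orientation contrasts are paired.

## What the synthetic generator does and does not emulate

`generate_ecosystem()` draws provision rates log-normally with
measure-specific scales (availability of order 1 per 100,000,
placement of order 30, workforce of order 12, utilisation of order
300 — magnitudes typical of regional mental-health provision) and
makes each utilisation output proportional to
$0.25 + 1.5\,\bar z_g$ (with $\bar z_g$ the DMU's normalised mean
provision in the output's care group) times log-normal noise of
sd 0.15. These constants were fixed once, a priori, to give
non-degenerate frontiers and positive provision–utilisation coupling.

The generator reproduces: the 19 × 57 shape, the naming taxonomy and
input/output split, positivity, and enough inter-DMU heterogeneity for
DEA to discriminate. It does **not** reproduce: real spatial
correlation, real scarcity patterns (true zeros in sparse areas),
expert appropriateness ranges, or any published league-table values.
Passing tests on synthetic data therefore validate the *machinery* —
sampling laws, LP correctness, indicator arithmetic, pre/post
bookkeeping — not any empirical claim about a real region. With 19
DMUs and scenario dimensionalities of 4–6 inputs and 2–5 outputs, a
large efficient share is expected (a known small-sample property of
DEA), and the synthetic pools show exactly that.

## Problem sizes used by the tests

The test suite validates the full reference cardinality — 19 DMUs ×
15 scenarios × 500 simulations × both orientations, 142,500 pool
records per orientation, about 16 s with the compiled solver — and
runs all other checks at reduced sizes (5–10 simulations, 2–3
scenarios) chosen to keep the whole suite around two minutes.
Moment-recovery checks use 10⁵ draws against closed-form triangular
and uniform moments at three standard errors; partition-of-unity
checks scan 10⁴ points per universe at 1e-12.

## Known limitations

* Day↔outpatient interrelations are not modelled; only residential
  variables receive rule-based range displacement.
* Only triangular, uniform and degenerate cell laws ship; the plan
  structure is extensible to other families (e.g. trapezoidal).
* The four scenarios of the published fifteen that were never
  enumerated variable-by-variable are not invented; the shipped
  configuration carries the eleven documented ones, and
  `fixture_scenarios()` pads with clearly-labelled synthetic fillers
  only for full-scale structural runs.
* The constant behind the published "efficiency error" column is
  unexplained and deliberately not reproduced by default.
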