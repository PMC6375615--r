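# rtesim

Stochastic efficiency analysis of small health areas, with fuzzy expert
interpretation of the data and decision-support reporting for
resource-shift interventions.

## Who this is for

Health-services researchers and regional planners who benchmark
comparable small health areas (the decision-making units, DMUs) on
their mental-health service provision and utilisation, and who need to
know not just *how efficient* each area is, but *how certain* and *how
stable* that assessment is, and *what would change* if staff, beds or
services were moved between areas.

## What it computes

**Relative Technical Efficiency (RTE).** Each DMU is scored in [0, 1]
by variable-returns-to-scale data envelopment analysis (the BCC
envelopment program with the convexity constraint Σλ = 1), two-phase:
the radial factor first (input orientation: min θ; output orientation:
max φ, reported as 1/φ so both orientations live on [0, 1]), then total
slack maximisation, which separates fully efficient units (RTE = 1,
zero slack) from weakly efficient ones (RTE = 1, residual slack). The
solver is a compiled two-phase primal simplex written for the many tiny
LPs this workload generates (~600k per full study).

**Monte-Carlo uncertainty.** The observed DMU × variable rate matrix
(default shape 19 × 57) is turned into a matrix of per-cell
distributions: triangular T[0.9·x, x, 1.1·x] by default, uniform
U[x, 1.1·x] for configured cells, degenerate for zeros. Each simulation
draws a full dataset realization, so the efficiency frontier itself is
resampled. A study runs `n_sim` simulations per scenario — named
input/output variable subsets encoding different "points of view"
(day care, outpatient care, workforce capacity, ...). Eleven
care-model scenarios ship in
`inst/extdata/scenarios-care-model.yaml`.

**Fuzzy expert interpretation.** Before scoring, sampled values can be
re-expressed relative to expert appropriateness ranges. Day-care (D)
and outpatient (O) provision are summarised into 0–100 construct
scores by five-set fuzzy partitions and product-sum gravity
defuzzification; "IF D/O is scarce THEN the residential floor is
higher"-style rules displace the appropriateness range of residential
variables (width preserved exactly); a piecewise-linear profile then
maps each value to its interpreted form.

**Distribution indicators.** Each pooled RTE distribution is binned
into 22 intervals (20 score bins plus weakly-efficient and efficient
bins) and summarised by class probabilities, moments, interval
stability `100 − 100(nint − 1)/(inttot − 1)`, density stability
`100 · (ln(100·acprob/nintprob) − minln)/(maxln − minln)`, their
weighted combination, and Shannon entropy with its percentage of
log₂(inttot).

**Interventions.** A management intervention is a list of explicit cell
edits (e.g. move 1 FTE psychologist between areas, converted to rates
per 100,000 via area populations). The pipeline reruns pre and post,
and reports Pre / Post / Variation (%) tables with t, Levene and
Kolmogorov–Smirnov tests at α = 0.05 and 0.01, globally, per scenario
and per DMU.

## Worked example

```r
library(rtesim)

ds   <- generate_ecosystem(fixture_config(), seed = 42)  # 19 x 57 synthetic
scen <- default_scenarios(ds)
cfg  <- pipeline_config(scen[c("S4", "S6")], n_sim = 200, seed = 42)

res <- run_pipeline(cfg, ds)
p6  <- subset(res$pool, orientation == "input" & scenario == "S6")
e   <- estimators(p6, above = 0.75)
sprintf("P(RTE=1)=%.4f  mean=%.4f  sd=%.4f  P(RTE>0.75)=%.4f",
        e$p_efficient, e$mean, e$sd, e$p_above)
#> "P(RTE=1)=0.9211  mean=0.9889  sd=0.0421  P(RTE>0.75)=1.0000"
stability_report(bin_pool(p6))
#> <stability_report> intstab = 76.19, denstab = 97.52, stab = 86.86,
#>                    entropy = 0.56 bits (12.52% of max)
```

So under outpatient-care framing (S6), this synthetic system is almost
always on or near the frontier (92 % of simulated scores are fully
efficient, mean RTE 0.989), and that verdict is stable: mass is
concentrated in few of the 22 intervals (stab ≈ 87/100) with low
entropy (13 % of the maximum) — data perturbations of ±10 % barely move
the assessment.

A resource shift of 4 outpatient staff per 100,000 between two areas:

```r
spec <- intervention_spec("I1", "reassign outpatient staff", data.frame(
  dmu = c("SHA03", "SHA11"), variable = "ProfTotO8+O10",
  change = c(-4, 4)))
study <- run_intervention_study(cfg, ds, spec)
study$reports$input$by_scenario$S6$stats[4:5, ]
#>   statistic        pre       post variation_pct
#> 4      mean 0.98887358 0.98886722 -0.0006434038
#> 5        sd 0.04205533 0.04208311  0.0660504937
```

The mean RTE moves by less than a thousandth of a percent and none of
the tests reject (t p ≈ 0.99, KS p = 1): a shift this small leaves the
efficiency picture intact — which is itself the decision-relevant
answer.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/rtesim simulate-data --out fx --seed 2
Rscript inst/cli/rtesim run --dataset fx/dataset.csv \
    --descriptors fx/descriptors.csv --scenarios fx/scenarios.yaml \
    --n-sim 100 --orientation both --seed 1 --out results
```

## Limitations

The synthetic generator reproduces the *shape* of real small-area
datasets (taxonomy, positivity, provision–utilisation coupling), not
real magnitudes; published league tables for any concrete region are
not reproducible without that region's dataset and its expert fuzzy
ranges. Day↔outpatient causal interrelations are not modelled; only
residential variables receive rule-based range displacement.
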