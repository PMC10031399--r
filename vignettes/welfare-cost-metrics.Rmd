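---
title: "Welfare-cost metrics for livestock LCA: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Welfare-cost metrics for livestock LCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(welfareLCA)
```

## The problem

Life-cycle assessment (LCA) compares production systems per *functional
unit* — here 1 kg of pig deadweight (DW) — but almost never includes animal
welfare, because welfare scores are not naturally expressed per unit of
product. This package implements a family of metrics that put farm-level
Welfare Quality (WQ) assessments on an LCA footing for breed-to-finish pig
systems, and the statistical machinery for asking how much the choice of
metric matters.

A breed-to-finish system has two assessed stages: sows and piglets (SP,
birth to weaning, plus the breeding herd) and fattening pigs (FP, weaning to
slaughter). Each stage carries four WQ principle scores in [0, 100] (good
health, good feeding, appropriate behaviour, good housing; 100 = best).

## The model

**Life-years per kg DW.** From an annualized production record we compute
the life-years each stage needs to produce 1 kg DW:

* SP life-years/yr = `sows_avg` (each breeding sow contributes her full
  on-farm year) + `born_alive_per_year * weaning_age / 365`;
* FP life-years/yr = `weaned_per_year * (slaughter_age - weaning_age) / 365`
  under the default mortality assumption: fattening animals that died on
  farm are credited the average age of those slaughtered. The alternative
  `death_at_weaning` mode credits only slaughtered pigs and bounds the
  sensitivity of that assumption from below; the relative gap between the
  two modes equals the post-weaning mortality fraction, which is a few
  percent in realistic herds.

Both are divided by the *effective deadweight*, which equates the two
co-products (fattening pigs and cull sows) by economic allocation:
`DW_eff = DW_fattening + DW_cull * price_cull / price_fattening`. This keeps
one functional unit with the fattening-pig kg as numeraire. The stage shares
`t_SP = y_SP / (y_SP + y_FP)`, `t_FP = 1 - t_SP` follow.

**Overall WQ score.** With principle weights `w` (presets: standard
0.35/0.25/0.25/0.15, equal, extreme 0.50/0.20/0.20/0.10 — reflecting the
lack of consensus on how much health should dominate),

```
overall = t_SP * sum_i(w_i * p_i^SP) + t_FP * sum_i(w_i * p_i^FP).
```

The same weights are applied to both stages; the API accepts a separate FP
weighting for sensitivity work, but no published weighting scheme
distinguishes stages.

**Welfare cost.** The headline metric converts quality multiplied by
quantity of life into a cost per kg DW:

```
cost = sum over stages s, principles i of
         (100 - p_i^s) * w_i * y_s   if p_i^s counts as a cost   (p < T)
         -p_i^s * w_i * y_s          if p_i^s counts as a benefit (p >= T)
```

Higher cost = poorer welfare; negative cost = net welfare benefit. The
transition `T` between cost and benefit is deliberately plural — there is no
consensus on where "life worth living" starts — so the canonical grid
crosses ten transitions (numeric T = 100, 90, ..., 40; the WQ
classifications *excellent* — all principles >= 55 and at least two >= 80 —
and *enhanced* — all >= 20 and at least two >= 55, evaluated per stage; and
behaviour-as-benefit, where the behaviour principle is always a benefit and
the other three always costs) with the three weightings: 30 variants.

The summand is discontinuous at `p = T` (crossing the transition drops the
contribution from `(100 - T) w y` to `-T w y`). This is implemented exactly
as defined, with no smoothing; users comparing systems near a transition
should be aware of it. For classification transitions, an excellent stage
also satisfies the enhanced transition (the definitions nest), and each
stage's flags are set by its own classification.

## Robustness statistics

Group comparisons use the tie-corrected Kruskal–Wallis test (midranks;
all-tied data are defined as H = 0, p = 1 since the tie-corrected
denominator vanishes), followed by Dunn's pairwise z tests with the pooled
tie-corrected variance, two-sided normal p-values and Holm step-down
adjustment within each omnibus family (not pooled across families, matching
per-figure letter displays). Compact letter displays use the
insert-and-absorb construction, so two groups share a letter iff they are
not significantly different. Ranking robustness across metric variants uses
Spearman correlations (Pearson on midranks, t approximation for p).

Systems sharing a breeding and/or rearing farm are not independent, and
there are too few of them to model the dependence; instead the statistics
are computed on an *independent subset*: connected components of the
shared-farm graph are taken as clusters (union-find), and one system per
cluster is retained uniformly at random under a named seed. Metric tables
always cover all systems.

The 5-point WQ indifference threshold (`biologically_different()`) is
reporting metadata only: it qualifies which significant differences are also
biologically meaningful, and never alters the tests.

## The synthetic population

The generator exists so the full pipeline is testable without the original
(restricted) farm dataset. Its defaults state a world calibrated to the
published summary facts only:

* 74 systems: none = 4, Red Tractor (incl. QMS) = 31, RSPCA assured = 12,
  free range = 18, woodland = 3, organic = 6;
* a sharing plan whose clusters (sizes 1-3, within label; size-3 clusters
  are breeding-farm + rearing-farm chains; breeding husbandry is a property
  of the breeding farm) collapse to exactly 43 independent systems;
* a target correlation of 0.57 between overall WQ score and total life-years
  per kg DW, on the independent subset;
* label orderings: woodland systems have the highest mean WQ scores and the
  lowest welfare costs, then organic, then free range / RSPCA assured
  (interchangeable), then Red Tractor, then unlabelled; outdoor breeding
  scores above indoor and outdoor finishing above slatted; woodland and
  organic need more life-years per kg DW than Red Tractor.

**Latent-quality construction.** One farm-level latent factor shifts all
eight principle scores (both stages) and, with a solved loading, the log of
the system's life-years multiplier. This is the simplest structure that
reproduces both the correlated principle scores and the positive
quality–life-years association. The loading is obtained by moment matching:
between-stratum moments are enumerated exactly over label × husbandry
strata (weighted by the *subset's* expected label composition, i.e. cluster
counts, because the published correlation refers to the subset), within-
stratum moments use the lognormal mixture with Stein's identity for the
covariance, and the loading solves the resulting equation (taking the root
of smallest magnitude when two exist). Measured over 200 seeds the mean
subset Pearson correlation is ≈ 0.58 against the 0.57 target; the residual
bias comes from truncating scores to [0, 100], which the linear moment
calculation ignores.

**Free parameters** (chosen once, as realistic for UK pig production, not
revisited): per-label mean principle scores spanning ~42–88 overall;
life-years multipliers 1.00–1.30; latent quality s.d. 3.5 and per-principle
noise s.d. 5 score points (within-label overall WQ s.d. ≈ 4.5); log
life-years residual s.d. 0.06; SP life-years share 0.237 ± 0.02; herd
baselines (150-sow median herds, 12% pre-weaning and 3% post-weaning
mortality, weaning at ~27 d indoor / ~40 d outdoor, 45% sow cull rate, 75 kg
cull DW, cull/fattening price ratio ≈ 0.5). Label score means and
multipliers were set by an a-priori power analysis so that the label-cost
ordering above holds by median in well over 95% of seeds, as the package's
own qualitative-replication tests require. Production records are
*back-solved* from the drawn life-years (deadweight per pig and slaughter
age are derived last), so the accounting module reproduces the drawn `y`
exactly — the generated slaughter ages (~170-250 d) and deadweights
(~80-95 kg) land in realistic ranges.

**What the generator does not emulate:** real WQ score distributions
(skewness, floor effects beyond truncation), seasonality, within-year herd
dynamics, non-random participation of farms, or any measure/criterion level
structure below the principle scores. A green qualitative-replication test
therefore establishes that the *pipeline* reproduces the published
structural findings on data with the stated statistical shape — not that
those findings hold for any real farm population.

## Numerical and design choices

* "Two greater than or equal to 80" is read as *at least* two (and likewise
  for enhanced); this is the convention that keeps classification monotone.
* Equal label precedence questions are resolved by the published
  least-to-most-demanding order: none < Red Tractor < RSPCA assured <
  free range < woodland < organic; Quality Meat Scotland is treated as Red
  Tractor.
* Pre-weaning piglet deaths: all born-alive piglets are credited the full
  pre-weaning period (parallel to the stated fattening-stage assumption; the
  source is silent for piglets).
* Sows contribute their full on-farm year: gestation + lactation cycles tile
  the productive year and the questionnaire data are annualized.
* A 365-day year; fractional ages in days are accepted.
* The quality–life-years association is exposed both as Pearson and Spearman
  (the published label "Pearson rank" is ambiguous); the acceptance target
  uses Pearson, whose degrees of freedom (41) match the subset size.
* Null-calibration caveat: with six label groups at the default sizes (min
  n = 3) the chi-squared reference for Kruskal–Wallis is intrinsically
  conservative (measured null rejection ≈ 0.041 at alpha = 0.05, identical
  for `stats::kruskal.test`); calibration checks therefore use three-level
  groupings with adequate sizes, where the measured rate is ≈ 0.048-0.050.
* All-equal data: Kruskal–Wallis returns H = 0, p = 1 by convention; Dunn z
  is 0 when the variance term vanishes.
* `welfare_cost` is validated against an independently coded 8-term
  summation to 1e-9 over the full 30-variant grid; the rank statistics are
  validated against hand-worked fixtures, base R implementations and
  20,000-draw permutation references.

## Limitations

The package consumes WQ principle scores; it does not compute them from
measures or criteria. Welfare at transport and slaughter, breeding boars and
upstream inputs (feed, gilts) are outside the system boundary. The metric
family inherits the WQ protocol's snapshot character, and the Eq.-level
discontinuity at each transition means small score differences near `T` can
flip a system between cost and benefit; the 30-variant grid is the intended
remedy — conclusions should be read across the grid, not from any single
variant.
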