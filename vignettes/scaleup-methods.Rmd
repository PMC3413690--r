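---
title: "Methods: projecting coverage scale-up to deaths averted, life expectancy and lifespan inequality"
author: "equilife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting coverage scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equilife)
```

## The problem

National decision-makers weighing child-health investments need to know what
scaling up a package of interventions — vaccines, case management, delivery
care — would buy, not only in deaths averted but in population-level outcomes:
the under-five mortality rate (U5MR), the neonatal mortality rate (NMR), life
expectancy at birth, and the distribution of age at death. `equilife`
implements that chain for a high-mortality setting of the Ethiopian type: a
coverage scenario feeds a cause-specific lives-saved cascade, the cascade's
averted deaths feed an abridged period life table, and the life table feeds
both the Chiang life expectancy and an extended Gini coefficient of lifespan
inequality.

## Coverage scenarios

A scenario names target coverages at an end year for a subset of
interventions; coverage moves from each intervention's baseline by **linear
interpolation**, one value per calendar year, with no sub-annual steps. This
is deliberately the simplest defensible scale-up shape: annual health-sector
plans are stated as endpoint targets, and any convexity assumption (logistic
uptake, front-loading) would have to be invented. Interventions outside the
scenario stay flat at baseline. A subcomponent intervention (see below)
inherits its parent's target unless the configuration overrides it, so both
"scaled with its parent" and "scaled on its own schedule" are expressible.

## The lives-saved cascade

Each intervention carries, per cause of death, an effectiveness $E$ (fraction
of deaths prevented at full coverage among those it can affect) and an
affected fraction $AF$ (share of the cause's deaths it can in principle
reach). The elementary step, for a cause with $D$ residual deaths and
coverage moving from $c_0$ to $c_t$, is

$$\text{averted} = D \cdot \frac{E \cdot AF \cdot (c_t - c_0)}{1 - E \cdot AF \cdot c_0}.$$

The denominator is the residual-counterfactual normalisation: the $D$ deaths
on input are deaths that occur *despite* baseline coverage, so the deaths
that full coverage could still avert are $D/(1 - E \cdot AF \cdot c_0)$
scaled by the remaining coverage gap. This is the standard lives-saved
convention; we state it prominently because published scale-up analyses
usually delegate it to modelling software without writing the formula.
$c_t < c_0$ (coverage loss) is allowed and produces a negative averted count
— a visible flag for a misconfigured scenario — rather than an error; the
degenerate case $E \cdot AF \cdot c_0 = 1$ is an error.

Interventions are applied **sequentially**: preventive interventions before
curative ones, in catalogue order within each class. Each intervention acts
on the residual left by the ones before it, so package members interact —
with a vaccine in the package there are fewer pneumonia cases left for case
management to treat, and dropping the vaccine inflates the case-management
attribution. Two algebraic facts are load-bearing and tested:

* the residual for a cause after the whole package is
  $D \prod_k \frac{1 - r_k c_{t,k}}{1 - r_k c_{0,k}}$ with $r_k = E_k
  \cdot AF_k$, so **total** package impact is invariant to the application
  order — only the attribution across interventions moves;
* removing an upstream intervention never decreases a downstream
  intervention's attribution for the shared cause.

**Subcomponents.** A subcomponent intervention (labor and delivery management
inside institutional delivery) is evaluated against the residual immediately
after its parent, recorded in the ledger, but does not reduce the residual
and is excluded from package totals. Its deaths are a refinement of the
parent's, and letting it also deplete the residual would double-count them
and break the conservation identity
$\text{baseline} = \text{residual} + \sum \text{averted}$ that holds per
cause and year over the non-subcomponent rows (relative tolerance $10^{-9}$
in the tests).

**Rates.** NMR is residual neonatal deaths per 1,000 live births. U5MR is
aggregated as a cohort probability,
$1 - (1 - q_{\text{neo}})(1 - q_{1-59})$ per 1,000, with
$q_{\text{neo}} = \text{neonatal}/\text{births}$ and $q_{1-59} =
\text{child}/(\text{births} - \text{neonatal})$, which avoids double-counting
denominators and reduces exactly to total under-five deaths per 1,000 live
births. Deaths averted are summed across the projection years for "by the
end year" totals.

## Life tables and life expectancy

The life table is an abridged **period** table on a 100,000-birth radix:
21 intervals (0, 1–4, then 5-year bands to the open 95+ interval) with death
counts per radix. The derived columns follow the classical method: survivors
$l$, interval death probability $q$, person-years
$L = n\,l(x+n) + a_x\,n\,d_x$, cumulative person-years $T$, expectancy
$e = T/l$, and $e(0) = T(0)/l(0)$. The calculations are deliberately
non-dynamic — a period table transformed in place, not a cohort-component
projection; that is a stated limitation of the approach, not an
approximation we could refine away within this design.

Numerical choices:

* **Separation fractions** $a_x$ default to 0.3 for [0,1), 0.4 for [1,5) and
  0.5 elsewhere (standard abridged-table practice, reflecting the
  concentration of infant deaths early in the first year); they are
  overridable per interval.
* **Terminal interval**: survivors entering the open interval live
  `terminal_expectancy` further years on average ($L = l \cdot e_{\text{term}}$,
  i.e. $L = l/m$ with $m = 1/e_{\text{term}}$), default 5 years beyond age
  95. This is a configuration knob: with a terminal expectancy set to $1/m$,
  a constant-hazard table recovers $e(0) = 1/m$ to well under 1%.
* **Applying averted deaths**: averted under-five deaths are removed from the
  [0,1) and [1,5) rows — 1–59-month deaths split between them by
  `post_neonatal_infant_fraction` (default 0.5; an infant mortality rate of
  68.5 alongside NMR 35 and U5MR 101 implies the post-neonatal-infant share
  of 1–59-month deaths is about 0.51) — and redistributed over the intervals
  above age 5 **proportionally to the baseline deaths there**. This is the
  simplest assumption consistent with an unchanged conditional mortality
  schedule above the affected ages, and it conserves the radix exactly.
* **Maternal extension**: current-life-table pipelines for child health do
  not carry maternal mortality, so averted maternal deaths are handled by the
  same mechanism, removed from reproductive-age intervals proportionally to
  births contributed (age-specific fertility rate × baseline person-years)
  and redistributed above the reproductive band. The maternal argument is a
  per-radix count, mirroring the under-five contract. A degenerate schedule
  with all fertility in one interval lands the whole adjustment there.

## Inequality in age at death

The distribution of age at death assigns each life-table interval one group
at its representative age $x + a_x n$ (the terminal group at
$x + e_{\text{term}}$) with weight $d_x/\text{radix}$ — the same $a_x$ as
the person-years arithmetic, keeping $e(0)$ and the inequality measure
internally consistent. Groups with equal age are merged before ranking, and
fractional ranks follow the convention that rank 1 is the best-off group
(highest age at death).

The inequality measure is the extended (single-parameter) Gini with
inequality-aversion parameter $v \ge 1$, evaluated **exactly** from the
piecewise-linear Lorenz curve $L(p)$ of the discrete distribution:

$$G(v) = 1 - v(v-1)\int_0^1 (1-p)^{v-2}\,L(p)\,dp.$$

$v = 2$ is the standard Gini; $v = 1$ is the aversion-free limit, exactly 0;
larger $v$ weights the earliest deaths more heavily. The design was
genuinely open here: the popular discrete plug-in
$G(v) = (v/\mu)\,\mathrm{cov}_f\!\left(h, (1-R)^{v-1}\right)$ with midpoint
fractional ranks coincides with the Lorenz form at $v = 2$ (both equal the
pairwise mean-absolute-difference Gini to machine precision, the defining
contract here), but for coarse distributions it is **not monotone in $v$** —
on a 50/50 distribution at ages 40/80 it gives $G(4) = 0.271 > G(5) =
0.260$ — whereas aversion monotonicity is exactly the property an
inequality-aversion parameter must have. We therefore use the Lorenz form,
keep the fractional ranks exposed on the distribution object, and assert the
$v = 2$ three-way identity (Lorenz = pairwise double sum = rank covariance)
in the test suite, with the explicit double-loop `gini_oracle()` as the
independent cross-check. The coefficient is scale-invariant, decreases when
all ages are shifted up, and for national populations typically lies between
0.10 and 0.50.

## The synthetic baseline

`make_baseline()` emulates an Ethiopia-like 2011 population so the whole
pipeline is testable without any download:

* life table targets: U5MR 101 and NMR 35 per 1,000 live births, life
  expectancy at birth 59.3 years. Under-five deaths are placed exactly
  (infant/child split consistent with an infant mortality rate of 68.5);
  adult mortality uses a flat background plus a Gompertz-type rise in age,
  with the overall scale calibrated by root-finding so $e(0)$ hits its
  target. The exact adult shape is a documented free choice — the source
  life tables of such analyses live inside modelling software and are not
  published.
* burden profile: 3,180,000 annual live births (with U5MR 101 this gives
  the familiar ≈321,000 under-five deaths a year) allocated across causes
  by the published cause-of-death fractions — neonatal causes 38% (split
  sepsis/asphyxia/prematurity), diarrhea 22%, pneumonia 12%, the remainder
  malaria, measles, HIV and other — plus maternal deaths at a maternal
  mortality ratio of 590 per 100,000.
* fertility: an Ethiopia-like age pattern over 15–49 with a total fertility
  rate near 3.9.

One feature is deliberate and worth knowing: published vital-statistics
rates (NMR 35, U5MR 101) and the published cause fractions (neonatal 38%)
are mutually inconsistent — 38% of 101 is a neonatal rate of 38.4, not 35.
The generator reproduces this tension rather than hiding it: the **life
table** carries the NMR-35 neonatal split, while the **burden profile**
follows the cause fractions (implied neonatal rate 38.4, matching the ~39
used in trajectory figures of such analyses). Projection trajectories
therefore start from the burden's rates; life-table outcomes start from the
vital-statistics rates.

All stochastic draws (catalogue effectiveness values, affected fractions,
baseline coverages) run through one seeded local stream that never touches
the global RNG state; the life-table calibration is deterministic, so a
config reproduces its baseline byte for byte. The generated catalogue mirrors
the published 14-intervention package's structure — classes, delivery
levels, targeted causes, the labor-and-delivery-management subcomponent —
with synthetic numeric values drawn from configurable ranges (effectiveness
from [0.15, 0.85], affected fractions from [0.3, 1], baseline coverage from
[0, 0.8] by default).

What passing tests on this baseline do and do not show: they demonstrate the
pipeline's internal coherence (conservation, monotonicity, order invariance,
the joint movement of U5MR down, $e(0)$ up and Gini down under scale-up) on
data with the right marginal structure. They do not validate the actual
effectiveness values, coverage data or cause-of-death surveillance of any
real country, and the synthetic adult mortality shape is one of many
consistent with the under-five and $e(0)$ targets.

## The packaged reference table

The printed deaths-averted table of the Ethiopian 2011–2015 scale-up
analysis is packaged verbatim (`table2_fixture()`) as the aggregation worked
example: 15 rows (14 interventions plus the subcomponent), per-scenario
target coverages and cumulative deaths averted, and the printed totals
(114,600 / 217,200 / 164,400). Two aggregation quirks are surfaced, not
reconciled:

* the Scenario 1 rows sum to 120,500 against the printed 114,600; the 5,900
  gap equals the improved-water-source and measles rows. `fixture_report()`
  reports both the computed row sum and the printed total, with their
  difference.
* the quoted top-five shares (57.8% and 65.7%) are shares of the *printed*
  totals; `fixture_report(share_basis = "printed")` reproduces them, with
  half-up rounding to one decimal as in the source.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at its
natural size — the 21-interval life table, the 15-row catalogue, 5
projection years — plus a 2,000-interval constant-hazard table for the
closed-form check and 1,000 random distributions for the Gini oracle sweep;
everything completes in seconds on one CPU. Every reported number is
recomputed at run time from the generator or the packaged table; reruns with
the same seed are identical.

## Known limitations

* The cascade is a deliberately transparent emulation of lives-saved
  arithmetic: no herd effects, no risk-factor (stunting/wasting) or
  birth-outcome sub-models, no uncertainty propagation on effectiveness.
* The life table is period and non-dynamic; saved children are aged into
  the existing mortality schedule rather than projected cohort by cohort.
* Costing, socioeconomic concentration indices (inequality over wealth
  ranks rather than age at death), and sub-national heterogeneity are out
  of scope.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
base <- make_baseline(cfg)
catal <- make_catalogue(cfg)
ids <- catal$interventions$id[is.na(catal$interventions$subcomponent_of)]
sc2 <- scenario("sc2", 2011, 2015, setNames(rep(0.9, length(ids)), ids))

pr <- project_scenario(base$burden, catal, sc2)
pr$trajectory
eq <- equity_trajectory(pr, base$life_table, base$burden$live_births,
                        fert = base$fertility)
eq

fixture_report("sc2", subset = top_five_interventions())
```
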