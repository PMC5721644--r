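---
title: "A Markov cohort model of early versus deferred panretinal photocoagulation"
author: "prpcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of early versus deferred panretinal photocoagulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prpcea)
```

## The decision problem

Panretinal photocoagulation (PRP) is conventionally given when diabetic
retinopathy reaches the high-risk proliferative stage (HR-PDR). Treating at
the earlier severe non-proliferative stage (severe NPDR) could prevent more
progression to blindness, at the price of treating people who would never
have progressed and of exposing them earlier to laser complications.
`prpcea` implements a state-transition (Markov) cohort model that weighs
this trade-off: a hypothetical cohort of 1000 patients with diabetes, aged
50, presenting with moderate NPDR, followed in 6-month cycles over 30 years
under two strategies — *usual care* (PRP at HR-PDR) and *intervention*
(PRP at severe NPDR). Costs (GBP, 2012/2013 prices, NHS and personal social
services perspective) and quality-adjusted life years (QALYs) are both
discounted at 3.5% per year, and the result is expressed as an incremental
cost-effectiveness ratio (ICER), or as dominance when one strategy is both
cheaper and more effective.

## Health states and disease dynamics

Disease severity runs

> moderate NPDR → severe NPDR → early PDR → HR-PDR → severe PDR → severe
> visual loss / blindness (SVL),

with clinically significant macular oedema (CSDMO) possible alongside any
tier from severe NPDR onwards, and death reachable from every state. Each
treatable state has a post-treatment (`_PT`) twin, giving 18 living states
plus an absorbing `dead` state (`health_states()`). Patients can progress,
regress one tier, develop CSDMO, remain where they are, or die; transitions
fire at the end of each cycle and no half-cycle correction is applied
(`settings$half_cycle_correction` exists for users who want the averaged
convention).

Transition rows are stored *conditional on surviving the cycle*. Each cycle
the engine applies death first — an age- and state-specific probability, see
below — and distributes the surviving mass over the stored row
(`build_cycle_matrix()`). This keeps externally supplied transition sets
usable unchanged, whatever mortality assumptions they were estimated under.

### How treatment is encoded

A treated state adopts the transition row of its post-treatment twin:
patients are treated during the cycle in which they occupy the state, and
end the cycle in the post-treatment lane (in the *corresponding*
post-treatment state unless the disease happened to move that cycle). We
deliberately did not encode treatment as a forced move that suspends disease
dynamics for a cycle: that one-cycle freeze falls at different disease tiers
in the two arms, which injects an artefactual QALY difference of its own and
breaks two properties we insist on — that a treatment with no effect and no
cost changes nothing, and that slowing progression can never *harm* the arm
that does it through the progression channel. Under the chosen encoding both
properties hold exactly (the test suite checks the null to 1e-12).

The two arms share one efficacy model and differ only in *when* PRP fires.
Post-treatment states progress more slowly in both arms; usual-care PRP is
not a pure cost.

## Mortality

General-population annual death probabilities come from a life table
(`age,annual_death_prob` CSV). Two hazard-scale multipliers adjust them:
a diabetes multiplier of 2.194, and a retinopathy-severity multiplier
(moderate NPDR 1.118, severe NPDR 1.422, mild PDR 0.992, moderate/high PDR
1.705; post-treatment states inherit their tier's class, and blindness is
assigned to the worst class as the nearest clinical neighbour). Annual
probabilities convert to cycle probabilities by the constant-hazard rule

$$p_{\text{cycle}} = 1 - (1 - p_{\text{annual}})^{rr \cdot \Delta t},$$

which can never exceed 1 — the reason the multipliers act on the hazard
(log-survival) scale rather than on probabilities directly. Whether the
severity multipliers *compose with* the diabetes multiplier
(`compose_diabetes = TRUE`, the default: both adjustments are described as
applied, and composition is the reading that uses both) or replace it is a
flag on the mortality model; the alternative reading is one switch away.

Two mortality quirks are worth knowing. First, the severity multipliers are
not monotone in tier: "mild PDR" (0.992) is *less* lethal than severe NPDR
(1.422). A consequence is that "faster progression always costs QALYs" is
not a theorem under these inputs — slowed progression keeps patients longer
in a more lethal pre-PDR state — although it holds throughout the region the
analyses use. Second, age advances by one cycle length per cycle from the
start age, and the life table is indexed by `floor(age)`.

## Costs and QALYs

Per cycle, a living state pays its scheduled visits (moderate/severe NPDR
tiers 1, early PDR 1.5, HR/severe PDR 2, blindness 0.5 visits; CSDMO and
post-treatment variants inherit their tier's count) at the ophthalmology
clinic rate of £106 by default — the split between £106 ophthalmology and
£80 monitoring visits is not pinned down by the sources, so the visit type
is configurable per state. Blindness additionally pays its £1483 annual cost
pro-rated to the cycle (residential care explicitly excluded). QALYs are the
state utility (five base-case values: NPDR tiers 0.7915, severe NPDR with
CSDMO 0.7365, PDR tiers 0.7047, PDR with CSDMO 0.6930, blindness 0.6218;
post-treatment states inherit their tier) times the cycle length.

Treatment events add: the PRP bundle, costed in the cycle the treatment
state is occupied — both eyes are treated together, by default two sittings
of two laser treatments (£131 each), £524 in all; the sources count only
laser treatments per sitting, so extra per-sitting clinic visits default to
zero but are a knob (`visits_per_sitting`). Treated patients who also have
CSDMO first receive focal laser to both eyes plus one OCT (£379). In the
cycle after treatment, a proportion of survivors suffers a one-cycle
complication: macular oedema (treated as the focal-laser + OCT bundle) or,
only when PRP is given at a severe PDR tier, vitreous haemorrhage
(vitrectomy, £989); the affected mass also takes a −0.03 utility decrement
for that single cycle. Complications are bookkept as a one-cycle attribute
of the post-treatment entry mass rather than as separate tunnel states —
identical arithmetic, smaller state space.

Discounting uses end-of-cycle factors $(1+r)^{-k\Delta t}$ for cycle
$k = 1, 2, \dots$, so the first half-year cycle is discounted at exponent
0.5. Whether the original analysis discounted its first cycle is unknowable
from the published totals (the choice moves QALYs in the fourth decimal);
`settings$discount_first_cycle = FALSE` switches to exponent zero.

## The parameter pack and the missing transition probabilities

Everything above lives in a single validated `parameter_pack`
(`base_case_pack()`, `load_pack()`, `write_pack()`): settings,
utilities, unit costs, resource profiles, one transition set per arm, and
the mortality model, serialised as YAML plus a life-table CSV so that the
transition sets can be replaced without touching code.

That swappability matters because the trial-derived (ETDRS) per-cycle
transition probabilities behind the original analysis are not publicly
available in machine-readable form. The
bundled pack therefore carries **synthetic placeholder transitions**,
flagged as such in their `source` field. Every published number that depends
on them — the base-case totals, the scenario tables, the tornado endpoints,
the "60% cost-effective" probability — is consequently *not* reproduced by
the bundled pack; what the package reproduces is the model's structure,
bookkeeping and analysis surface, into which the real set can be dropped.

## The synthetic-data generator

`synthetic_scenario()` fixes the generator's knobs; `make_pack()` produces a
full, always-valid pack from them. The generator emulates: a parametric
Gompertz–Makeham life table ($p(x) = a + b e^{cx}$, default
$a = 5\times10^{-4}$, $b = 10^{-5}$, $c = 0.11$, giving 0.3% annual
mortality at 50 rising to 6.7% at 80 — deliberately milder than a real
general-population table); time-homogeneous transition rows that place a
progression probability on the next-worse tier, a regression probability on
the next-better one, a CSDMO incidence on the sideways sibling, and the
remainder on staying; and the treatment wiring described above. The
untreated and post-treatment lanes are anchored at moderate NPDR (regression
from the first post-treatment tier returns there, from where renewed
progression leads to re-treatment), so the lanes are topologically parallel
and slowed progression can only help.

Defaults, chosen once as clinically plausible values and not revisited:
progression 0.08 per half-year (most of a surviving cohort reaches PDR
within the horizon), regression 0.02, CSDMO incidence 0.02 per cycle at any
tier with a CSDMO sibling, treatment effect 0.5 (earlier laser roughly
halves progression, in line with the effect sizes early-treatment trials
reported for severe visual loss), post-PRP macular oedema 0.10 and vitreous
haemorrhage 0.02 per treated patient (neither probability appears in the
published base case).

What the generator does *not* emulate: calibration to any trial data;
time-varying (duration-dependent) transition rates, although the engine
itself rebuilds the matrix every cycle and supports them through the pack;
asymmetric two-eye disease; type 1 versus type 2 diabetes. Passing tests on
generated packs therefore demonstrate correctness of the machinery and the
qualitative mechanism — earlier effective treatment preserves sight-years —
not agreement with any published cohort.

With the complication channel active, the effect direction is *not*
guaranteed by construction, and that is intentional: a near-null treatment
effect combined with a high complication rate makes early treatment a net
QALY loss (everyone treated, nobody helped), which is precisely the
clinical trade-off the model exists to weigh. The test suite asserts the
unconditional direction with complications off, the non-negative direction
across the base-case grid with them on, and the sign reversal in the
harmful corner.

## Sensitivity analyses

**One-way / tornado.** Any of the five utility values, seven unit costs or
four visit counts can be scaled by a low/high multiplier pair (default
±50%, utilities capped at 1.00), both arms rerun deterministically, and the
net monetary benefit $\mathrm{NMB}(\lambda) = \lambda\,\Delta E - \Delta C$
evaluated (default λ = £20,000/QALY). Bars are ranked by width. Parameters
whose scaled values collide with the cap compress accordingly — visible for
the larger utilities.

**Scenarios.** `scenario_timing()` rewires the intervention arm to treat on
occupancy of the early PDR tiers (severe NPDR tiers revert to their
untreated rows); the usual-care arm is untouched by construction.
`scenario_sittings()` delivers the PRP course in 1, 2 or 4 sittings; it is a
cost-only scenario — complication risk is held constant — so QALYs are
bit-identical to the base case and the cost shift equals the sitting-bundle
difference times the discounted treated mass (the suite checks both).

**Probabilistic.** `sample_psa()` draws every unit cost from a gamma
distribution and every utility value (plus the complication-disutility
magnitude) from a beta distribution, method-of-moments matched to
$(\mu, \sigma)$, then reruns both arms per iteration; 1000 iterations by
default. No standard errors were published for these inputs, so the
defaults are the field's common fallback — σ = 20% of the mean for costs,
10% for utilities — and both fractions are prominent knobs
(`psa_spec()`), because the cost-effectiveness probability read off the
acceptability curve moves directly with them; any such probability should be
quoted together with the σ assumption. Parameters are drawn independently
(only marginal families are specified), and transition probabilities are
*not* varied by default; an optional Dirichlet resampler
(`vary_transitions`) is provided for users who want structural uncertainty.
Since base-case transitions and mortality are fixed, the cohort trace is
computed once and only the payoffs are re-accrued per iteration, which is
why 1000 iterations take well under a second. The CEAC counts iterations
with strictly positive incremental NMB, so exact ties favour usual care and
the two strategies' probabilities sum to one.

## Numerical conventions and degenerate inputs

Row-stochasticity is enforced at load time to 1e-9; the engine conserves
cohort mass to the same tolerance over all 60 cycles. A zero standard error
in the PSA yields degenerate draws that reproduce the deterministic result
exactly (same code path, no tolerance). Beta moment-matching is refused,
naming the parameter, when $\sigma^2 \ge \mu(1-\mu)$. Equal-QALY
comparisons award the verdict to the cheaper arm and define no ICER; the
exactly-equal case is reported as `equivalent`. Utilities scaled past 1.00
in the one-way analysis are capped there, as published sensitivity analyses
do.

## Problem sizes

The shipped analyses use the study conditions themselves: 60-cycle
deterministic runs (milliseconds), 16-parameter tornado (~0.6 s), and
1000-iteration PSAs (~0.4 s). The property-style tests run hundreds of
full cohort evaluations across randomized scenarios and finish in a few
seconds.

## Known limitations

* The bundled transition probabilities are structural placeholders, not
  trial estimates; no published total should be expected from the default
  pack (see above).
* Utility values amalgamate disease tiers (early and severe PDR share one
  value), which compresses exactly the gradient early treatment exploits.
* The severity-mortality multipliers are non-monotone across tiers, with
  the consequences noted under *Mortality*.
* One price year (2012/2013), no societal costs, no anti-VEGF comparator,
  no type 1 / type 2 stratification, no per-eye asymmetry.
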