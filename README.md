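# prpcea

A Markov cohort cost-effectiveness model of **early versus deferred
panretinal photocoagulation (PRP) in diabetic retinopathy**, for health
economists and ophthalmology researchers who want a fully inspectable,
re-parameterisable implementation of the decision problem: treat at severe
non-proliferative retinopathy (severe NPDR), or wait until high-risk
proliferative retinopathy (HR-PDR)?

## The model

A cohort of 1000 patients with diabetes, aged 50, presenting with moderate
NPDR, is followed in 6-month cycles over 30 years through the severity
chain

    moderate NPDR → severe NPDR → early PDR → HR-PDR → severe PDR → SVL/blindness

with clinically significant macular oedema (CSDMO) variants, post-treatment
(PT) states, and death. Annual life-table mortality is adjusted on the
hazard scale for diabetes (×2.194) and retinopathy severity
(×1.118/1.422/0.992/1.705) and converted to cycle probabilities by
*p* = 1 − (1 − *p*ₐ)^(rr·Δt). Each strategy accrues discounted (3.5%/year)
costs (GBP 2012/2013, NHS/PSS perspective) and QALYs; results are reported
as increments ΔC, ΔE with an ICER or a dominance verdict, and as net
monetary benefit NMB(λ) = λ·ΔE − ΔC. Deterministic one-way (tornado) and
scenario analyses, and a probabilistic sensitivity analysis (gamma costs,
beta utilities; cost-effectiveness plane and acceptability curve over
λ = £0–£50,000) sit on top.

The trial-derived per-cycle transition probabilities behind the original
analysis were never published in machine-readable form: the bundled
parameter pack carries clearly flagged **synthetic placeholder transitions**
(see the methods vignette, `vignettes/prp-timing-model.Rmd`). Real sets drop
in through the YAML pack format without touching code.

## Worked example

```r
library(prpcea)

pack <- base_case_pack()   # base-case settings + placeholder transitions
run  <- run_comparison(pack)
run$usual_care$result
#> <strategy_result> usual_care: cost £4361.51, 10.7865 QALYs (discounted)
run$intervention$result
#> <strategy_result> intervention: cost £4128.95, 10.9907 QALYs (discounted)
run$comparison
#> <comparison_result> ΔC = £-232.56, ΔE = 0.2042 QALYs: intervention_dominant
nmb(run$comparison, 20000)
#> [1] 4317.241
```

Under the default pack, treating early costs £233 *less* per patient and
yields 0.20 more QALYs over 30 years — early PRP **dominates** deferred PRP
(cheaper and more effective, so no ICER is defined), and at a willingness
to pay of £20,000/QALY the intervention is worth £4,317 per patient in net
monetary benefit. Sensitivity analyses:

```r
scenario_sittings(pack, 1)$intervention$result$cost  # PRP in one sitting
#> [1] 3900.75
one_way(pack, "utilities.svl", c(0.5, 1.5), wtp = 20000)[, c("nmb_low", "nmb_high")]
#>    nmb_low nmb_high
#> 1 5260.193 3374.289   # the better blindness is tolerated, the less early PRP is worth

res <- sample_psa(pack, psa_spec(iterations = 1000, seed = 1))
ceac(res)[41, ]  # λ = £20,000
#>     wtp p_intervention p_usual_care
#> 41 20000          0.933        0.067
```

The 93% acceptability figure depends directly on the assumed parameter
standard errors (none were published; defaults are 20% of the mean for
costs, 10% for utilities) — see the vignette before quoting it.

## The analysis workflow

The full study pipeline is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_build_inputs.R   # write + round-trip the parameter pack
Rscript analysis/02_base_case.R      # deterministic base case
Rscript analysis/03_scenarios.R      # treatment timing; 1/2/4 PRP sittings
Rscript analysis/04_tornado.R        # ±50% one-way DSA on NMB at £20k/QALY
Rscript analysis/05_psa.R            # 1000-iteration PSA, CE plane, CEAC
```

Each step prints what it found and writes its tables (and a JSON run
manifest) under `results/`.

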