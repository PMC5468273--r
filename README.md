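# aquaflux

Analysis toolkit for the functional characterization of aquaporin (AQP)
water and solute channels — the assay chain used when candidate channel
genes from an insect (or any animal) are expressed in *Xenopus laevis*
oocytes, profiled by qPCR, and silenced in vivo:

* a **forward model of oocyte swelling** under osmotic and solute
  gradients (single compartment, conserved internal osmolytes, coupled
  water/solute fluxes);
* **permeability estimation**: the osmotic water permeability coefficient
  *P*<sub>f</sub> and the solute permeability coefficient *P*<sub>s</sub>
  from cross-sectional area time courses,

  *V*/*V*₀ = (*A*<sub>t</sub>/*A*₀)^(3/2),  
  *P*<sub>f</sub> = *V*₀ · d(*V*/*V*₀)/d*t* / (*S* · *V*<sub>w</sub> · Δosm),

  with per-oocyte initial-slope fits, mercury-inhibition summaries, and
  the standard group statistics (Welch t-test / one-way ANOVA + Tukey);
* **relative expression** by the 2^(−ΔΔCt) method with a dilution-series
  amplification-efficiency gate (0.9 ≤ E ≤ 1.1) and RNAi knockdown time
  courses with matched-day controls and off-target checks;
* **phenotype endpoints** for blood-fed bugs: percent of the meal excreted
  over 24 h, excreta urea back-calculated from a colorimetric standard
  curve, engorgement, and fecundity comparisons with effect sizes;
* **seeded synthetic generators** for every assay, so the full chain is
  testable, and power/calibration questions answerable, without
  laboratory data.

The package follows the classic R modelling idiom: `fit_swelling()`
returns a classed object with `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate` methods.

## Worked example

Five oocytes expressing a high-efficiency water channel against five
water-injected controls, simulated at the reference assay conditions
(200 → 70 mOsm challenge, 60 s record), then fitted:

```r
library(aquaflux)

aqp <- sim_swelling_cohort(swelling_sim_params(
  pf_true = 2e-2, n_oocytes = 5, area_noise_cv = 0.005, seed = 101))
aqp$group <- "ClAQP1"
ctl <- sim_swelling_cohort(swelling_sim_params(
  pf_true = 1e-3, n_oocytes = 5, area_noise_cv = 0.005, seed = 102))
ctl$group <- "control"
ctl$oocyte_id <- paste0("c_", ctl$oocyte_id)

fit <- fit_swelling(rbind(aqp, ctl), mode = "water", window = 20)
summary(fit)
#> Group Pf estimates (cm/s), window 20 s:
#>     group n      mean       sd       sem
#> 1  ClAQP1 5  0.020434 0.002145 0.0009593
#> 2 control 5 -0.001059 0.002652 0.0011860
#> 8 low-R^2 fit(s) flagged
#>
#> Welch two-sample t-test: t = 14.09 , p = 9.379e-07
#>   difference of means: 0.02149  (95% CI 0.01795 to 0.02504)
```

The channel-expressing group recovers the generating *P*<sub>f</sub> of
2×10⁻² cm/s (small downward bias is expected: the osmotic gradient
dilutes as the cell swells across the 20 s fit window). The control
group's *P*<sub>f</sub> is statistically zero — its fits are flagged for
low R², which is exactly what a water-tight oocyte's noise-dominated
record should look like; flagged fits are kept, never dropped.

A knockdown Ct table and an excretion phenotype, analyzed the same way:

```r
tab <- sim_ct_table(c(dsGFP = 1, dsAQP1 = 0.1), n_replicates = 3,
                    ct_noise_sd = 0.2, seed = 7)
relative_expression(tab, calibrator = "dsGFP")
#>    group   gene delta_ct delta_delta_ct   rq rq_lo rq_hi
#> 1 dsAQP1 target     7.82           2.84 0.14 0.117 0.167
#> 2  dsGFP target     4.97           0.00 1.00 0.765 1.308

bugs <- sim_bug_cohort(phenotype_sim_params(effect_multiplier = 0.5,
                                            seed = 11))
endpoint_comparison(bugs, "excretion_24h")
#> Welch two-sample t-test: t = 7.877 , p = 6.256e-07
#>   difference of means: 4.696  (95% CI 3.433 to 5.958)
```

The injected group shows ~86% transcript knockdown (RQ 0.14), and halving
the excretion rate costs the treatment bugs about 4.7 percentage points
of meal excreted by 24 h.

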