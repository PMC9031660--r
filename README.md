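# synergyci

Quantitative analysis of drug-combination cytotoxicity by the median-effect
method: dose–response fitting, combination index (CI) and dose-reduction
index (DRI) for constant-ratio two- and three-drug regimens, plus the
supporting quantifications of an in-vitro chemosensitization study —
viability normalization, Annexin-V/PI apoptosis quadrants, DNA-content
cell-cycle fractions and doubling-time estimation — and synthetic-data
generators that make the whole pipeline testable without laboratory files.

It is aimed at researchers evaluating chemosensitizers (the motivating use
case is Disulfiram combined with cisplatin and paclitaxel in ovarian cancer
cell lines) who want the classical Chou–Talalay quantities computed
reproducibly from tidy plate-reader CSVs.

## The model

Each agent's cytotoxicity follows the median-effect equation

    fa / fu = (D / Dm)^m,        fu = 1 - fa

with `Dm` the median-effect dose (the model IC50) and `m` the sigmoidicity.
It is fitted by least squares on the linearized plot
`log10(fa/fu) = m·log10(D) − m·log10(Dm)`. A constant-ratio mixture is
fitted as a composite agent on total dose; at effect level `fa` the
combination index and per-drug dose-reduction indices are

    CI(fa)  = Σ_i D_i / Dx_i(fa)         (CI < 1 synergism, = 1 additive, > 1 antagonism)
    DRI_i   = Dx_i(fa) / D_i             with identity CI = Σ_i 1/DRI_i

where `D_i = w_i · D_total(fa)` are the component doses inside the mixture
and `Dx_i(fa)` the single-agent dose producing the same effect. Every
reported CI row is audited against the reciprocal-DRI identity.

## Worked example

Simulate single-agent plates for two drugs, fit them, build an
IC50-ratio combination with a true CI of 0.5, and recover it:

```r
library(synergyci)

cisplatin  <- drug_truth("cisplatin",  m_true = 2.0, dm_true = 22,   noise_sd = 0.02)
paclitaxel <- drug_truth("paclitaxel", m_true = 2.0, dm_true = 0.38, noise_sd = 0.02)

plate_cis <- simulate_plate(cisplatin,  seed = 11)
plate_pac <- simulate_plate(paclitaxel, seed = 12)
fit_cis <- fit_median_effect(fa_table(plate_cis)$dose_uM, fa_table(plate_cis)$fa)
fit_pac <- fit_median_effect(fa_table(plate_pac)$dose_uM, fa_table(plate_pac)$fa)
fit_cis
#> Median-effect fit
#>   m  = 2.0545
#>   Dm = 22.549 (dose at fa = 0.5)
#>   r  = 0.9994  (n = 8, excluded = 0)

design <- combination_design(c("cisplatin", "paclitaxel"),
                             basis = c(fit_cis$Dm, fit_pac$Dm))
mix <- simulate_combination(list(cisplatin, paclitaxel),
                            combo_truth(design, ci_profile = 0.5),
                            noise_sd = 0.02, seed = 13)
tab <- fa_table(mix)
combo_fit <- fit_median_effect(tab$dose_uM, tab$fa)
fa_ci_curve(design, combo_fit,
            list(cisplatin = fit_cis, paclitaxel = fit_pac))
#>    fa   ci classification dose_cisplatin dose_paclitaxel dri_cisplatin dri_paclitaxel
#>  0.50 0.49      synergism           5.52          0.0917          4.08           4.08
#>  0.75 0.49      synergism           9.57          0.1589          4.02           4.15
#>  0.90 0.49      synergism          16.59          0.2755          3.96           4.22
```

The fitted IC50s land within a few percent of the generating values (22 and
0.38 µM); the estimated CI sits at 0.49 across the IC50–IC90 range against
a true value of 0.5, classified as synergism, and each DRI says the
respective drug's dose can be cut about 4-fold inside the mixture at equal
effect. `reduced_dose(22, 4.08)` then gives the reduced cisplatin
concentration such a combination would need.

A full multi-drug analysis (IC50 table plus CI/DRI tables from one YAML
config) runs through `run_synergy_analysis()`; see
`inst/extdata/preset_skov3ip1.yaml` for a complete configuration and
`inst/scripts/run_synergy.R` for a shell wrapper. Apoptosis and cell-cycle
quantification are exposed as `quadrant_classify()` /
`cell_cycle_fractions()`, and growth curves as `doubling_time()`.

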