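# retnet — double-loop neural-network estimation of metal retention

`retnet` estimates the retention of heavy metals (Zn, Cr, Cu, Pb) in the
human body from easily measured quantities — metal concentrations in
drinking water and soil plus basic physiology — instead of invasive
biosubstrate assays. It is aimed at environmental-health and
biomonitoring researchers who have cohort tables of exposure and
clinical measurements and want a trainable, fully reproducible
implementation of the double-loop multi-neural-network approach.

## The statistic and the model

Direct measurement of retention is impractical, so it is derived from
renal clearance. For a metal *M*, the clearance (mL/min) follows the
Reberg formula

    CL_M = (c_urine * D) / (c_blood * 1440 * BS)

with `c_urine`, `c_blood` the metal concentrations in urine and blood
(µg/mL), `D` the daily diuresis (mL), 1440 the minutes in a day and `BS`
a Mosteller-style body-surface correction normalising kidney filtration
to the population-average 1.73 m². Retention is then an exponential
transform of clearance in units of the cohort spread σ:

    Retention_M = exp(-CL_M² / (2σ²))  ∈ (0;1]

Zero clearance (no excretion) means maximal retention 1; retention
decreases strictly with clearance.

Two single-hidden-layer perceptrons per metal map exposure to retention:

* **long-term block** (7 inputs): weight, height, body area, age, sex,
  metal in drinking water, metal in soil — soil being a depository
  medium that integrates chronic exposure;
* **short-term block** (6 inputs): the same minus soil.

Each block has 5 hidden `tanh(0.7x)` neurons and a linear output, is
trained for 10,000 epochs of full-batch resilient backpropagation
(RPROP, step-shrink 0.5, step-growth 1.2, initial step 0.5) on its own
80/20 split, with features and target affinely mapped to [−1, 1] on the
training split. The **closed double-loop model** fuses the two blocks
with confidence coefficients derived from their aggregate test errors:

    a_l = Err_T(l) / (Err_T(l) + Err_T(s)),   a_s = 1 − a_l
    Retention_M = a_l * Retention_M^l + a_s * Retention_M^s

Because the study's clinical cohort is private, the package ships a
seeded synthetic-cohort generator (`simulate_cohort()`) with the same
schema and demographic structure (242 children/teenagers, 54 boys) and a
planted monotone exposure→clearance mapping, so every part of the
pipeline can be trained and validated against known ground truth.

## Worked example

```r
library(retnet)

coh <- simulate_cohort(cohort_config(n = 200, seed = 42))
fit <- double_loop(coh, "pb", seed = 42, gross_filter = TRUE)
fit
#> Double-loop retention model — PB
#>   long block : 7-5-1, train err 0.001155, test err 0.003248
#>   short block: 6-5-1, train err 0.007549, test err 0.008838
#>   confidence : a_l = 0.2687, a_s = 0.7313 (error_proportional)

predict(fit, coh[1:3, ])
#>   retention_l retention_s retention
#> 1      0.0253      0.0033    0.0092
#> 2      0.6336      0.6908    0.6755
#> 3      0.9306      0.9225    0.9246
```

The per-block errors are mean squared deviations on the normalised
[−1, 1] scale (so 0.0032 ≈ a 5.7% RMS deviation of the scaled output);
the short-term block tests worse here, and the error-proportional
confidence scheme weights it 0.73. `predict()` returns both block
estimates and the fused retention per subject — row 1 is a low-retention
subject (high clearance), row 3 a high-retention one; the fused value
always lies between the two block outputs. Reference targets for these
rows were 0.019, 0.610 and 0.921.

Five-fold validation with contiguous windows shifted sequentially from
the first element:

```r
cross_validate(coh, "pb", seed = 42, gross_filter = TRUE)
#> 5-fold sequential-shift validation — PB (seed 42)
#>          mean       sd
#> long  0.008322 0.010740
#> short 0.019710 0.009350
#> fused 0.003183 0.001602
```

Models persist as versioned JSON (`save_model()` / `load_model()`) and
reload with bit-identical predictions. A command-line surface over the
same functions lives at `inst/cli/retnet.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","retnet.R",package="retnet"))') generate --n 100 --seed 7 --out cohort.csv`, then `train`,
`evaluate`, `crossval`, `predict`).

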