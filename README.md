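# blastkin

Mechanistic simulation of serum amyloid-beta 42 (Aβ42) kinetics after
repeated low-level blast overpressure (BOP) exposure, for researchers
studying blood biomarkers of blast neurotrauma in weapons-training cohorts.

The package chains three models and a validation layer:

1. **Blast dose → mechanical damage.** Each blast event (peak BOP in psi)
   injects a pulse into a damage state `R_M` with linear recovery
   `dR_M/dt = S(t) − (α/t_d)(R_M − λ)`. Below the injury threshold
   (θ = 4, proportional to 4 psi) the residual damage λ is zero and
   recovery is complete; above it `λ = c_λ(BOP − θ)`, leaving chronic
   residual damage. The damage peak sits ~0.5 s after the event.
2. **Phasic biological responses.** Hyperacute and acute states follow
   `dR_B1/dt = k_in R_M − k_out1 R_B1/(R_M + R_M0)` and
   `dR_B2/dt = k_out1 R_B1 − k_out2 R_B2`; clearance slows while damage
   persists, so repeat blasts inside the recovery window add onto
   unresolved state.
3. **Amyloid production and whole-body PBPK transport.** The hyperacute
   response amplifies APP synthesis, `k_APP = k_APP0 (1 + x R_B1)`
   (calibrated x = 1.5); APP → C99 → Aβ cleavage feeds Aβ42 into brain
   interstitial fluid, which exchanges with brain vasculature (LRP1/P-gP
   efflux, RAGE influx, bidirectional BBB flux), perivascular/glymphatic
   space, plasma, peripheral tissue and lymph by mass-balance ODEs. Serum
   predictions are the plasma compartment, normalized to each subject's
   day-1 pre-training draw.
4. **Calibration and validation.** One shared x is fitted by bounded least
   squares on normalized draws (an exact linear superposition makes the
   objective one-dimensional and cheap); accuracy is scored as signed
   relative percent error with cohort summaries, an exact paired Wilcoxon
   signed-rank test of pre- vs post-training accuracy, over-approximation
   fractions, and error-vs-demographics regressions. A seeded synthetic
   cohort generator emulates the 15-subject, three-day 0.50-caliber
   training design so the whole pipeline runs without any external data.

## Worked example

```r
library(blastkin)

# three training days at 5, 6.5 and 8 psi average BOP
sched   <- training_schedule(3, daily_bop = c(5, 6.5, 8))
subject <- subject_scenario("S1", sched)
series  <- predict_serum(subject)
predicted_draws(series)
#>   sample_label time_h serum_pg_ml serum_normalized
#> 1       d1_pre   6.52    20.00000         1.000000
#> 2      d1_post  16.40    20.90426         1.045213
#> 3       d2_pre  30.52    25.00868         1.250434
#> 4      d2_post  40.40    23.10384         1.155192
#> 5       d3_pre  54.52    29.53793         1.476896
#> 6      d3_post  64.40    26.05602         1.302801
```

Serum starts at the 20 pg/mL baseline (normalized 1 by construction at the
day-1 pre-training draw, 2.48 h before training). Each supra-threshold day
raises the prediction — +4.5% by the first post-training draw — and the
residual damage keeps the model elevated into following mornings, the
model's signature over-approximation of pre-training draws when measured
levels return to baseline overnight.

Calibration on a synthetic cohort recovers the generating amplification:

```r
cohort <- generate_cohort(cohort_design(noise_cv = 0, seed = 1))
fit    <- fit_amplification(cohort)
fit$estimate
#>   x
#> 1.5
```

And the packaged per-subject validation errors of the training cohort
reproduce its summary statistics:

```r
validation_report(load_validation_errors())
#> $mean_abs_error_pct  6.494667
#> $sd_abs_error_pct    5.210192
#> $wilcoxon            W = 106, n = 15, p = 0.006714
#> $frac_pre_overapprox 0.8
#> $r2_age              0.00716 ; $r2_service 0.0413
```

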