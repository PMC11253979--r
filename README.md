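# renalclock

Sex-specific, circadian-regulated simulation of sodium transport and
oxygenation in the rat kidney.

Sodium reabsorption is the kidney's dominant oxygen sink, and both the
filtered load and the apical transporters recovering it (NHE3, SGLT1,
NKCC2, NCC, ENaC) oscillate with the circadian clock and differ between
male and female rats. Because the renal medulla is poorly perfused, the
balance of oxygen consumption against delivery decides how close the
outer medulla runs to hypoxia over the day, between the sexes, and
under diuretic treatment. `renalclock` is a reduced-order steady-state
model of that balance, intended for renal physiologists and modellers
who want a small, fully transparent surrogate of the published
predictions of detailed epithelial-transport models: every equation is
a few lines of R, every parameter is visible, and a full recalibration
takes seconds.

## The model

* **Circadian drivers.** Each clock-regulated quantity follows
  `X_p(t) = X_p0 (1 + γ_p sin(2π (t + 6 − θ_p)/24))` with tabulated
  amplitudes/peaks (GFR 14%/ZT18, NHE3 40%/ZT14, SGLT1 20%/ZT14, NKCC2
  20%/ZT14, NCC 20%/ZT14, ENaC 56%/ZT14, renal blood flow 20%/ZT10).
* **Nephron chain.** A representative nephron (population-weighted
  SNGFR: 35 nl/min male, 28 female; 36,000 nephrons/kidney; plasma Na⁺
  144 mmol/L) feeds ten lumped segments, PCT → PST → thin limbs → mTAL
  → cTAL → DCT → CNT → CCD → OMCD → IMCD. Active reabsorption in a
  segment is `f_a · Na_in · m(t)^β` (driver multiplier `m`, sublinear
  exponent `β`); passive (paracellular) reabsorption `f_p · Na_in`
  exists only in the proximal tubule. Mass balances exactly.
* **Oxygen budget.** `Q_O2_active = T_Na_active / 15` (3 Na⁺ per ATP ×
  5 ATP per O₂); basal consumption is fixed at 25% of baseline total.
  Efficiency is `T_Na_total / Q_O2_total` (mol Na⁺ per mol O₂).
* **Outer-medullary pO₂.** `pO2 = (D_O2 − X_O2 − Q_O2_med)/α` with
  delivery `D_O2 = MRBF × CaO2` (MRBF 2.26/1.81 mL/min male/female,
  `CaO2 = 1.34·Hb·SaO2 + 0.003·PaO2`), a 2.6% vasa-recta shunt, and α
  calibrated per sex so the daily-mean pO₂ is 22.5 mmHg.
* **Interventions.** Loop diuretic: NKCC2 scaled by `1 − ε·i(t)` with
  80% inhibition in the dark and 70% in the light phase (ε calibrated).
  ENaC inhibition: distal active transport scaled by the inhibited
  fraction (100% by default).
* **Calibration.** The 33 free transport parameters are fitted by
  deterministic Levenberg–Marquardt least squares to a registry of
  published model predictions (segmental and regional transport ratios,
  oxygen-consumption differences, excretion levels, diuretic
  responses). The shipped fit is in `inst/extdata/calibrated_params.yaml`
  and is regenerated by `calibrate()`.

## Worked example

```r
library(renalclock)
m <- kidney_model()           # calibrated two-sex model
simulate_kidney(m, "male", zt = 14)
#> <kidney_state> male rat, ZT14, intervention: none
#>   filtered Na+ 194.14 umol/min; urine Na+ 0.270 umol/min (0.14% of filtered)
#>   filtered volume 1348.2 uL/min; urine volume 1.50 uL/min
#>   total T_Na (umol/min): cortex 138.2, medulla 55.6, whole kidney 193.9
```

At the active-phase peak (ZT14) the male kidney filters 194 µmol/min of
sodium (7% above its daily mean of 181) and reabsorbs 99.9% of it,
cortical segments carrying ~2.5× the medullary transport. The oxygen
side:

```r
kidney_oxygen(m, simulate_kidney(m, "male", 14))
#> <oxygen_budget> male rat, ZT14, intervention: none
#>   region na_total qo2_active qo2_basal qo2_total efficiency
#>   cortex   138.24      6.110    1.8950     8.005      17.27
#>  medulla    55.63      3.193    0.9649     4.157      13.38
#>    whole   193.87      9.302    2.8599    12.162      15.94
po2(m, "male", c(2, 14))
#> [1] 20.11 24.89
```

Whole-kidney consumption is 12.2 µmol O₂/min at ZT14 with the proximal-
rich cortex transporting sodium more efficiently (17.3 mol Na⁺/mol O₂)
than the medulla (13.4), and the predicted outer-medullary oxygen
tension rises from 20.1 mmHg at ZT2 to 24.9 mmHg at ZT14. A loop
diuretic given to a female at ZT14:

```r
compare_scenarios(m, "female", 14, intervention_spec("loop_diuretic"))
#>      sex zt  intervention        metric control treated fractional_change
#> 1 female 14 loop_diuretic medullary_qo2   3.678   3.334           -0.0935
#> 2 female 14 loop_diuretic medullary_po2  24.833  25.540            0.0285
#> 3 female 14 loop_diuretic      urine_na   0.393   0.489            0.2443
#> 4 female 14 loop_diuretic       urine_v   2.184   2.718            0.2443
```

Medullary oxygen consumption falls 9.4%, medullary pO₂ rises 2.9%, and
sodium and volume excretion rise 24% — and the same call for a male
shows a smaller relative pO₂ gain, the model's expression of the
greater benefit of loop diuretics to female medullary oxygenation.

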