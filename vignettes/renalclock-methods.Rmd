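---
title: "Modelling circadian and sex differences in renal sodium transport and oxygenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian and sex differences in renal sodium transport and oxygenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalclock)
```

## The problem

Renal sodium reabsorption is the kidney's dominant oxygen-consuming
process, and both the filtered sodium load and the apical transporters
that recover it are under circadian-clock control and differ markedly
between the sexes. Because the renal medulla is poorly perfused, the
balance between time-varying oxygen consumption and time-varying oxygen
delivery decides how close the outer medulla runs to hypoxia, and how
that risk changes over the day, between males and females, and under
diuretic treatment.

`renalclock` is a reduced-order steady-state model of this balance for
the rat kidney. It is deliberately small — ten lumped nephron segments,
seven sinusoidal clock drivers, and an algebraic oxygen budget — and its
free parameters are calibrated, by deterministic least squares, to the
quantitative predictions published for a detailed epithelial-transport
model of the same system. It is a tool for exploring the published
predictions, their internal structure and their sensitivities, not a
replacement for the full epithelial model.

## Circadian drivers

Every clock-regulated quantity is a sinusoid
$$X_p(t) = X_{p,0}\left(1 + \gamma_p \sin\frac{2\pi (t + 6 - \theta_p)}{24}\right),$$
with $t$ the zeitgeber time (ZT; lights-on at ZT0 starts the rest phase
of a nocturnal rodent), $\gamma_p$ the fractional amplitude and
$\theta_p$ the peak time. The tabulated set is GFR (14%, ZT18), NHE3
(40%, ZT14), SGLT1 (20%, ZT14), NKCC2 (20%, ZT14), NCC (20%, ZT14),
ENaC (56%, ZT14) and renal blood flow (20%, ZT10). Amplitudes and peaks
are shared between the sexes; the sex differences live in the mean
transport parameters. Drivers are stored as dimensionless multipliers
(mean 1), so the same table modulates any physical mean.

The literature also contains a larger (~40%) day-night renal blood flow
variation; the tabulated 20% amplitude is used throughout, and the RBF
amplitude is exposed as an override for users who want to explore the
larger value.

The canonical evaluation grid for daily means (baseline references, the
oxygen-tension calibration, daily-mean consumption) is hourly — 24
points are exact for sinusoid means and cheap for everything else.

## Nephron population and filtered load

Six nephron classes (one superficial at 2/3 of the population, five
juxtamedullary at 0.4/3 … 0.05/3) are collapsed into one representative
nephron with the population-weighted single-nephron GFR: 35 nl/min in
males (30/45 superficial/juxtamedullary) and 28 nl/min in females
(24/36), a fixed 1.25 male/female ratio. Whole-kidney quantities use
36,000 nephrons per kidney and plasma Na⁺ 144 mmol/L — standard rat
values chosen once, because the source predictions are per kidney
without stating either number. Every calibrated quantity is a ratio or
percentage and is insensitive to both conventions; absolute µmol/min
outputs scale with them and are flagged as convention-dependent.

## The segment chain

The chain runs PCT → PST → thin limbs → mTAL → cTAL → DCT → CNT → CCD →
OMCD → IMCD, with the fixed region map cortex = {PCT, cTAL, DCT, CNT,
CCD} and medulla = {PST, thin limbs, mTAL, OMCD, IMCD}. For a segment
with delivered sodium $N_{in}$:

* active reabsorption $= f_a\,N_{in}\,m(t)^{\beta}$, where $m(t)$ is the
  segment's driver multiplier (PCT/PST: 0.9·NHE3 + 0.1·SGLT1; TALs:
  NKCC2; DCT: NCC; CNT through IMCD: ENaC; thin limbs: none);
* passive (paracellular) reabsorption $= f_p\,N_{in}$, non-zero only in
  PCT and PST — net paracellular transport in the TAL and distal
  segments is set to zero;
* the total is clipped at 99.5% of delivery, passive taking precedence.

The exponent $\beta \ge 0$, shared within each driver group (PT, TAL,
DCT, ENaC) and per sex, makes transport sublinear in transporter
activity. This is the reconciliation device between two published
facts: transport changes proportionally with luminal flow, yet the
published circadian transport increments are much larger than the
±7% filtered-load swing. Linear activity dependence cannot produce both.

Water handling is deliberately coarse: proximal segments are
iso-osmotic (volume follows the local total sodium fraction), thin
descending limbs reabsorb a fixed 30% of delivered volume, TALs are
water-impermeable, the DCT takes a fixed 10%, and the four ENaC
segments reabsorb a baseline fraction $w_d$ (calibrated, per sex)
modulated by the local sodium fraction through a coupling constant
$\lambda = 1$ — so 100% ENaC inhibition also releases distal water.
Final urine volume is closed by a fixed urinary sodium concentration of
0.18 µmol/µL (≈180 mM, a typical rat value): terminal water
reabsorption is adjusted so urine leaves at that concentration, bounded
by the delivered volume and the 99.5% reabsorption cap. This closure is
the reduced model's free-water handling; it makes fractional diuresis
track fractional natriuresis, which is the right level of detail for a
chain that does not resolve medullary osmotic gradients.

Mass is conserved exactly at every segment and at the whole-kidney
level (filtered = reabsorbed + excreted, for sodium and volume), and
the test suite verifies this against an independent segment-by-segment
re-summation on 200 generated parameter sets at 10⁻⁹ relative
tolerance.

## Oxygen budget

Active transport converts to oxygen consumption through the
Na-K-ATPase stoichiometry — 3 Na⁺ per ATP, 5 ATP per O₂ —
$$Q_{O_2}^{active} = T_{Na}^{active}/15 .$$
Basal consumption is fixed at 25% of total consumption under baseline
conditions (all drivers at their mean), i.e.
$Q_{O_2}^{basal} = \tfrac{1}{3}Q_{O_2}^{active\,*}$, and does not vary
with time. The whole-kidney 25% split is applied segmentwise in
proportion to baseline active consumption, which preserves the global
ratio and makes regional aggregation exact. The basal share is
overridable (reported range ~25–30%).

Transport efficiency is $T_{Na}^{total}/Q_{O_2}^{total}$ (mol Na⁺ per
mol O₂): 15 for purely active transport with no basal load, 11.25 at
baseline, and higher wherever passive transport contributes — hence
structurally higher in the proximal tubule than in the TAL or distal
segments, and nearly constant over the day because both transport and
its oxygen cost scale together with flow.

## Outer-medullary oxygen tension

The medullary balance is
$$p_{O_2}(t) = \frac{1}{\alpha}\left(D_{O_2}(t) - X_{O_2}(t) - Q_{O_2}^{med}(t)\right),$$
with delivery $D_{O_2} = \mathrm{MRBF}(t)\times C_{aO_2}$ (medullary
blood flow 2.26/1.81 mL/min male/female carrying the RBF driver;
arterial content $C_{aO_2} = 1.34\,\mathrm{Hb}\,S_{aO_2} +
0.003\,P_{aO_2}$ with Hb 146/141 g/L, saturation 0.95, arterial
pressure 88 mmHg), a fixed 2.6% vasa-recta shunt, and the simulated
medullary consumption. Oxygen volumes convert to moles at 22.4 mL/mmol.
The conversion factor $\alpha$ is calibrated per sex so the daily-mean
pO₂ equals 22.5 mmHg (both sexes anchored at the same mean), and is
never recalibrated under an intervention — treated pO₂ values are
predictions. The measured reference profile (mean 22.5 mmHg, amplitude
8%, peak ZT13) is available as `experimental_po2()`; its ZT14-over-ZT2
rise is ≈16.7%.

## Interventions

*Loop diuretic*: the NKCC2 driver of both TALs is multiplied by
$1 - \varepsilon\, i(t)$ with $i = 0.8$ in the dark phase (ZT12–24) and
$0.7$ in the light phase — the schedule reflecting circadian organic-
anion-transporter-mediated drug secretion — while SNGFR stays at
control values. The single efficacy $\varepsilon \in (0,1]$, shared
across sexes and phases, absorbs everything the reduced model cannot
represent (notably the interstitial-gradient washout) and is calibrated
jointly with the transport parameters against the published medullary
consumption reductions (9.2% inactive / 8.4% active phase). Whether the
drug also reaches the cortical TAL is not settled; both TALs are
inhibited here, and results are reported for the medulla.

*ENaC inhibition*: active transport in CNT, CCD, OMCD and IMCD is
multiplied by $1 - $ (inhibited fraction), directly (not through the
exponent), so 100% inhibition zeroes distal active transport exactly.
Comparisons run at ZT0 and ZT12.

## Calibration design

The free parameters — per sex: nine active fractions, two proximal
passive fractions, four group exponents, one distal water fraction;
plus the shared $\varepsilon$ (33 in all) — are fitted by
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on log-ratios
of model quantities to the published values, under box bounds, from the
fixed initial point documented in `default_segment_params()`. There is
no randomness anywhere in the pipeline; repeated runs are
bit-identical, and refitting a perfect (surrogate) registry from its
optimum is a fixed point.

The registry and its weights encode a feasibility analysis worth
stating plainly. The published circadian-swing percentages (segmental
+47/34/16% male, +38/49/26% female; oxygen consumption +43/39/48%) are
*jointly incompatible with mass conservation* in any chain that filters
only ~15% more sodium at ZT14 than ZT2 and excretes ~1% of the load: a
weighted sum of segmental increments cannot exceed the filtered-load
increment by more than the urinary slack. These targets therefore
carry weight 0.3 — they pull the exponents toward sublinearity but are
allowed large residuals — while the mutually consistent targets
(regional sex ratios, whole-kidney consumption sex difference, urinary
excretion levels, connecting-tubule delivery ratios, per-sex diuretic
reductions) carry weight 1–3. Four one-sided margin terms penalize
violations — and only violations — of the published orderings (female
above male oxygenation gain; male above female ENaC natriuresis).
Weak priors hold the segmental shares at the stated physiology
(proximal > half, TAL most of the remainder, distal ≈10%; females
shifted from proximal to TAL/DCT), and a small ridge (0.02) toward the
initial point regularizes directions the registry leaves
under-determined, such as the CCD/OMCD/IMCD split. For parameter-
recovery studies the ridge is set to zero; the group exponents are then
recovered from surrogate registries to ~10⁻¹⁴.

The shipped parameter file (`inst/extdata/calibrated_params.yaml`) is
the output of `calibrate()` on this registry and is regenerated by the
same call; `kidney_model()` reads it by default.

## Known limitations

* **Circadian swings are capped by conservation.** The calibrated
  whole-kidney transport and oxygen-consumption rises from ZT2 to ZT14
  are ~15–21%, not the published ~43%: with a 14% GFR amplitude the
  load rises 15%, and a mass-conserving chain cannot amplify that to
  40%+ without physiologically absurd urinary swings. The published
  percentages originate from a model whose printed numbers are not
  simultaneously satisfiable under this constraint; the fit distributes
  the tension and the acceptance suite records the discrepancy openly.
* **Distal deliveries run anti-phase to transporter activity.** The
  connecting-tubule delivery is higher at ZT0 than ZT12 (+35% male, as
  published) precisely because upstream transporters are near nadir at
  ZT0; by the same mechanism, simulated urinary excretion peaks in the
  light phase, opposite to real rats. Only the filtered load (proximal
  delivery) genuinely peaks in the dark phase here.
* **The ENaC timing ordering is out of reach.** With fraction-based
  distal transport, the fractional response to 100% ENaC inhibition at
  time $t$ is $1/\mathrm{esc}(t) - 1$, where $\mathrm{esc}(t)$ — the
  distal escape fraction — depends only on ENaC activity at $t$. ENaC
  activity is lower at ZT0 than ZT12, so the simulated male response is
  necessarily larger at ZT12, whereas the published comparison (driven
  by delivery-dependent distal fluxes in the full model) has it larger
  at ZT0. The male-above-female orderings, which are delivery-driven,
  do hold.
* Volume handling is a closure, not a mechanism: urinary osmolality,
  medullary gradients and free-water regulation are not modelled; the
  male/female distal *volume* delivery ratios are consequently not on
  the fitting surface (the sodium ratios are).
* No potassium, chloride or other solutes; no transepithelial
  potential; no TAL paracellular secretion; no tubuloglomerular
  feedback; no per-nephron-class heterogeneity; steady states only.

## What the generated test data do and do not show

Property tests run on randomly perturbed but valid parameter sets
(reproducible from a stated seed via `generate_fixtures()`): they
establish conservation, monotonicity and flow-proportionality of the
*solver* over the admissible parameter space, and exponent recovery
establishes identifiability of the *calibration* on registries the
model can fit exactly. None of this validates the reduced model against
real measurements — the only empirical anchors are the published
values in the registry, with the caveats above.

## Problem sizes and runtimes

The chain is ten algebraic segments, so a full two-sex simulation at
one time point is microseconds; a complete calibration (≈40–60
Levenberg–Marquardt iterations over 33 parameters, each iteration
simulating ~60 scenarios) takes a few seconds on one core. The test
suite uses 200 perturbed parameter sets for the conservation oracle and
hourly grids (24 points) for all daily means.
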