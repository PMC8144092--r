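---
title: "Circadian heart-rate and electrolyte rhythms in simulated QT and drug-induced QTc prolongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian heart-rate and electrolyte rhythms in simulated QT and drug-induced QTc prolongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circaqt)
```

## What the pipeline computes

`circaqt` chains five model layers:

1. **Circadian inputs.** A log-linear regression of the RR interval on sex,
   age and clock time, and cosinor models of plasma K⁺, Na⁺ and Ca²⁺. These
   are deterministic functions of (sex, age, hour); subject-level random
   effects (a multiplicative RR offset, additive ion offsets) displace them
   per individual.
2. **Virtual population.** Demographics (sex split, uniform ages over a
   range) plus the random effects and lognormal conductance scale factors
   that create inter-subject electrophysiological spread.
3. **Cell and fibre electrophysiology.** The ten Tusscher–Panfilov 2006
   (TT06) human ventricular myocyte model, three transmural variants,
   coupled into a 1D monodomain cable (endo:mid:epi = 50:30:20) and paced at
   the epicardial end. Plasma electrolytes enter as the extracellular
   concentrations of the Nernst/GHK terms — the mechanistic route by which
   electrolyte rhythms move repolarisation.
4. **Pseudo-ECG and QT.** A unipolar extracellular potential
   $\phi(x^*) \propto -\int \partial_x V_m \,\partial_x(1/r)\,dx$ at an
   electrode on the fibre axis 2 cm beyond the non-paced end; QT is the
   interval from the stimulus to the tangent-method T-wave end.
5. **Pharmacology and statistics.** Hill pore block of IKr/IKs/INa/ICaL from
   unbound concentrations (synthetic one-compartment BID profiles with an
   extensive/poor-metaboliser clearance split), and thorough-QT statistics:
   study-specific or individual QT correction, time-matched change from the
   drug-free baseline, mean/SE/upper-95%-CI summaries.

## Key parameters and defaults

| Parameter | Default | Units | Note |
|---|---|---|---|
| Diffusion coefficient D | 0.0016 | cm²/ms | monodomain cable |
| Space step Δx | 0.01 | cm | 165-node fibre at 1.65 cm |
| Time step Δt | 0.01 (0.02 fast) | ms | explicit stability D·Δt/Δx² = 0.16 |
| Pre-pacing | 100 (30 fast) | beats | single-cell, per cell type |
| Fibre beats | 3 (2 fast) | beats | last beat measured |
| Stimulus | −52 µA/µF, 2 ms, 10 nodes | | see "Numerical choices" |
| Electrode | 2 cm beyond non-paced end | cm | unipolar convention |
| K⁺ cosinor | 4.088/4.213 ± 0.18, peak 10:07 | mM | female/male mean |
| Na⁺ cosinor | 138.169/140.096 ± 1.1, peak 13:08 | mM | |
| Ca²⁺ | 2.313/2.418, no rhythm | mM | |
| RR offset CV | 8% | | lognormal, multiplicative |
| Ion offset SD | 0.35 / 2.0 / 0.10 | mM | K/Na/Ca, additive |
| Conductance CV | 15% | | GKr/GKs/Gto/GCaL, lognormal |
| PK: ka, V, CL(EM), CL(PM) | 3 h⁻¹, 100 L, 30, 6 L/h | | one-compartment, BID to day 4 |
| PM fraction, fu, CL CV | 0.07, 0.037, 30% | | CYP2D6-like bimodality |
| Tolterodine MW | 325.49 | g/mol | ng/mL ↔ µM |

Inter-subject variability magnitudes are package defaults chosen to give a
population QT spread of a few tens of ms; they are configurable and are not
claimed to equal any clinical estimate. The PK generator reproduces the
*structure* of tolterodine exposure (Tmax ≈ 1 h at the default ka, BID
accumulation to steady state by day 4, a right-skewed bimodal Cmax
distribution, dose proportionality), not calibrated absolute exposures; see
"Known limitations".

## Design choices in the circadian layer

* The RR regression uses the natural logarithm with RR in ms
  (exp(7.163) ≈ 1290 ms is a physiological intercept; base 10 would not be).
* The quadratic age term enters with a positive sign; with it a 30-year-old
  man at noon has ≈ 78 bpm, whereas a negative sign would give an implausible
  127 bpm.
* Acrophases written as clock times (10:07, 13:08) are converted to decimal
  hours, and phases to radians as 2π/24·(h − acrophase).
* Calcium has no circadian term, so the model returns the sex mean plus the
  subject offset. Published logit-scale calcium means exist (−0.5 female,
  0.1 male) but the bounds of that transform are not available; a two-point
  inversion would pin an approximate range ≈ [2.04, 2.76] mM yet assumes a
  shared range across sexes, so the forward model deliberately does not use
  it.
* In the "HR-only" scenario electrolytes are frozen at the subject-specific
  24-h mean (mesor + offset); in the fully frozen scenario everything holds
  its hour-0 value.

## Numerical choices

* **Integrator.** Rush–Larsen exponential updates for the 12
  voltage-dependent gates (tabulated on a 0.05 mV grid per run; the `fCass`
  gate, which depends on subspace calcium, is updated exactly), forward
  Euler for voltage, concentrations and the release gate. Δt = 0.01 ms
  default. The exported right-hand side avoids the tables entirely so
  derivative-level comparisons are exact.
* **Discretisation.** A literal reading of a 0.01 *mm* space step with
  D = 0.0016 cm²/ms and Δt = 0.01 ms would give a stability factor of 16 —
  violently unstable for any explicit scheme — so the space step is taken as
  0.01 cm (0.1 mm), the common TT06 cable discretisation, giving factor 0.16
  and a 165-node fibre at 1.65 cm. Both steps are configurable; the solver
  refuses configurations with D·Δt/Δx² ≥ 0.5 and names the offending triple.
* **Stimulus.** A 1 ms, −52 µA/µF stimulus confined to 3 end nodes does not
  capture in this discretisation: with a diffusion length of ≈ 0.11 cm over
  2 ms, the injected charge spreads into the cable faster than it
  depolarises the stimulated nodes. The default fibre stimulus is therefore
  −52 µA/µF for 2 ms over the 10 nodes (0.1 cm) at the pacing end, verified
  to capture every beat across the physiological CL/electrolyte/block range.
* **Per-time-point protocol.** Every subject-hour is an *independent* run:
  each cell type is pre-paced single-cell (default 100 beats) at that hour's
  cycle length, electrolytes and block, then the fibre runs a few beats and
  the last is measured. This mirrors a short-run (≈10 s per time point)
  simulation protocol and captures the *acute* electrolyte response. The
  alternative — chaining hours so cells fully re-equilibrate — would
  suppress the potassium effect entirely: at true steady state TT06
  repolarisation is almost insensitive to Ko (301.1 ms at Ko 5.4 vs
  300.5 ms at 3.9, CL 1000), because intracellular K⁺ drifts to compensate,
  whereas the acute response to Ko 5.4 → 4.0 is ≈ +7 ms.
* **T-wave end.** Tangent method: steepest return of the T wave towards the
  isoelectric level (median of the 30 ms before the measured beat's
  stimulus), extrapolated to its baseline crossing. Flat T waves (< 1% of
  QRS amplitude) or missing crossings are flagged and excluded from
  summaries with a count; a run aborts if more than 20% of measurements are
  flagged.
* **Seeds.** A master seed derives per-subject child seeds through a counter
  scheme, so adding subjects never reshuffles existing ones, and the sex
  sequence is a deterministic interleaving whose prefixes are stable.
  Given a configuration and master seed, every output is bit-identical
  across runs.

## Verification strategy

The compiled cell model is checked against an independent R transcription of
the TT06 equations integrated with `deSolve` (derivatives agree to ~1e-15
relative; a full paced beat agrees within 1 mV at a resolved step), and
against published TT06 physiology: steady-state epicardial APD90 of
≈ 301 ms at CL 1000 ms, resting potential ≈ −85 mV, M-cell APD longest.
Property-style tests assert the physiological response directions (APD and
fibre QT increase with cycle length, with IKr block, and with decreasing
extracellular K⁺), mesh-convergence of the measured QT (< 2 ms on halving
Δx and Δt), exact recovery of correction exponents on noise-free power-law
data, and per-subject |corr(QTcI, RR)| < 0.05 after individual correction.

The shipped test suite runs the two study designs at reduced size so the
whole suite stays within a routine CI budget: the diurnal study uses
6 subjects × 24 hours with the fast solver profile (50-cell fibre,
Δt = 0.02 ms, 30 pre-pacing beats, 2 fibre beats), and the virtual trial
6 subjects × 3 protocol times × {baseline, 2 mg, 4 mg}. The full-size
designs (53 subjects; 10 × 48 subjects) are available through the same
configuration objects.

## What the synthetic layers do and do not emulate

The synthetic PK stage stands in for a physiologically based tolterodine
model. It reproduces the features the QT analysis consumes — absorption with
Tmax ≈ 1 h, accumulation to steady state under BID dosing, dose
proportionality, and the CYP2D6-driven bimodal, right-skewed exposure
distribution in which some therapeutic-dose subjects reach
supratherapeutic-dose concentrations — but its default absolute exposures
are those of the stated one-compartment parameters, not of a calibrated
PBPK model. Consequently the *absolute* mean QTc changes of the virtual
trial depend directly on those defaults, and passing the trial's ordering
and null checks does not certify exposure realism.

The virtual population emulates printed demographics (53 subjects, 53%
female, ages 18–49 uniform) and adds plausible but unverifiable biological
variability. Passing tests on this population demonstrates internal
consistency of the pipeline, not agreement with any individual clinical
cohort.

## Known limitations

* **Diurnal QT amplitude.** With TT06 and the direct plasma→extracellular
  mapping, the simulated mean diurnal QT amplitude is a few ms (rate
  adaptation contributes ~2–4 ms over RR 770–993 ms at the shipped
  pre-pacing depth; the ±0.18 mM K⁺ rhythm ~±1 ms). Clinically reported
  amplitudes are ~24 ms (QT) and ~17 ms (QTcI). TT06's shallow steady-state
  rate adaptation and mild Ko sensitivity cannot reproduce those magnitudes;
  the corresponding end-to-end checks in the test suite document this
  honestly as failures rather than relaxing their bands. The *qualitative*
  pattern — sinusoidal QT, longer at night, strictly larger within-subject
  variability when electrolyte rhythms are on — is reproduced.
* **Trial effect sizes.** With the shipped PK defaults the 2 mg/4 mg mean
  QTc changes at Tmax are ≈ 9–10 and ≈ 17–18 ms — the right ordering and
  roughly double ratio, but larger than the ~4 and ~8 ms reported for
  tolterodine, consistent with the synthetic exposures exceeding calibrated
  unbound concentrations. Supplying measured concentration–time profiles via
  `load_pk_csv()` removes this layer entirely.
* No placebo arm is simulated; the drug-free baseline plays that role, so
  the reported change-from-baseline equals a placebo-adjusted change by
  construction.
* The pseudo-ECG is a single unipolar lead from a 1D strand: no torso
  geometry, no 12-lead reconstruction, no dispersion biomarkers beyond QT.
* Cell geometry/capacitance are the fixed TT06 constants; age- or
  sex-specific cardiomyocyte scaling is out of scope (fibre length is the
  only geometric degree of freedom, configurable per sex).
* The metabolite of tolterodine (5-HMT) and multi-drug interactions are not
  modelled; block is a static pore block without kinetics or trapping.

## Reproducing a study end-to-end

```r
library(circaqt)
cfg <- study_config(scenario = "circadian_hr_ions",
                    pop_spec = population_spec(n_subjects = 53,
                                               prop_female = 0.53),
                    hours = 0:23, solver = solver_spec(),
                    correction = "individual", seed = 20260929)
res <- run_smetana_study(cfg)        # ~hours at full resolution
write_study_outputs(res, "smetana-out")
```

Every output directory contains the measurement tables and a JSON manifest
with the full configuration and master seed from which the run can be
reconstructed exactly.
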