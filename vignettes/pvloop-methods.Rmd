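---
title: "Pressure-volume loop analysis and the elastance simulator: models, parameters, and design choices"
author: "pvloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-volume loop analysis and the elastance simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvloop)
```

## What this package computes

Invasive pressure-volume (PV) loop analysis characterizes left-ventricular
(LV) function from simultaneous LV pressure and volume, as acquired with a
conductance catheter. From each cardiac cycle one obtains the loop's corner
coordinates (EDV, ESV, EDP, ESP), the derived global indices (SV, EF, SW,
CO, CI, SVI), contractility measures (PRSW, dP/dt extremes, the
end-systolic elastance Ees from the ESPVR, the Starling contractile index),
diastolic measures (the relaxation constant Tau, end-diastolic stiffness
Eed from the EDPVR), and afterload/interaction measures (arterial elastance
Ea = ESP/SV, valvulo-arterial impedance Zva, and the ventricular-arterial
coupling ratio). This package implements that full battery for severe
aortic-stenosis recordings obtained before and after transcatheter valve
replacement, together with the cohort statistics such pilot studies use
(exact paired Wilcoxon, Mann-Whitney subgroup deltas, Kendall tau-b,
Pearson), a 40-point loop canonicalization/averaging step, and — because no
clinical recordings are distributed — a lumped-parameter cardiovascular
simulator whose ground truth validates every estimator by parameter
recovery.

## The simulator

### Model structure

The ventricle follows the classical time-varying elastance hypothesis:

$$P_{LV}(t) = E(t)\,\bigl(V(t) - V_0\bigr),$$

with $E(t)$ sweeping from a diastolic floor `emin` (the generative analog
of Eed) to the end-systolic value `emax` (the analog of Ees) along a
normalized double-Hill activation curve

$$\phi(s) \propto \frac{(s/a_1)^{n_1}}{1+(s/a_1)^{n_1}}
             \cdot \frac{1}{1+(s/a_2)^{n_2}}, \qquad s = t/T,$$

a standard smooth waveform whose two factors give independent control of
the activation rise ($a_1$, $n_1$) and of the timing and abruptness of
relaxation ($a_2$, $n_2$). Relaxation rate, and hence the Tau the analysis
side measures, is governed mainly by $n_2$ (larger = faster decay).

Ejection passes a Gorlin-type quadratic orifice,
$\Delta P = (q/(K\,\mathrm{EOA}))^2$ in series with the characteristic
impedance $Z_c$ of a three-element Windkessel ($Z_c$, $R_p$, $C$); filling
comes from a constant-pressure venous reservoir through a mitral
resistance. The state equations (LV volume and Windkessel pressure) are
integrated with fixed-step RK4 at a 1 ms internal step — the system is not
stiff and a fixed step makes runs bit-reproducible across platforms — and
resampled to the requested output rate. Cumulative in/outflow integrals are
carried as extra RK4 states so volume conservation can be checked against
the integrator itself (residuals are at machine precision).

The first 10 beats are a discarded warm-up from arbitrary initial
conditions; emitted samples start in periodic steady state. With all
variability off, consecutive emitted beats agree in EDV to < 0.05 ml.

### Stochastic structure

* RR intervals: i.i.d. Gaussian jitter with coefficient of variation
  `rr_cv` (truncated at 3 SD). Sinus rhythm uses 0.02. The "AF" label uses
  0.10 — deliberately milder than clinical AF (cv 0.15-0.25), because the
  steady-state machinery excludes beats whose RR deviates more than 20%
  from the running median, and at clinical AF variability that rule would
  discard ~40% of beats and leave essentially no contiguous analysis
  window. The label marks irregular-RR physiology while keeping the
  pipeline exercisable.
* Preload: the venous pressure carries a beat-to-beat AR(1) fluctuation
  (SD 1 mmHg, lag-1 correlation 0.7). This is what spreads EDV across
  beats and makes the PRSW/ESPVR/EDPVR regressions identifiable — the
  natural-variability analog of a caval-occlusion run.
* Ectopics: with probability `ectopic_rate` a beat is short-coupled (RR
  60% of the mean) with contractility scaled 0.7, followed by a
  compensatory pause (RR 140%); this produces exactly the aberrant loops
  the exclusion step must catch, and the simulator logs the truth.
* Measurement noise: additive white Gaussian on the emitted channels,
  defaults 1 mmHg and 2 ml — conductance-catheter scale.

All randomness flows from one integer seed; with the stochastic amplitudes
at zero the seed has no effect.

### Default parameters — the study conditions

Defaults were fixed once to reproduce a severe-aortic-stenosis cohort at
rest as reported invasively in such patients: HR ~65 bpm, EDV ~90 ml,
LVEDP ~15 mmHg, ESP ~135-150 mmHg, SW ~6400 mmHg ml, Tau ~37 ms, dP/dt
~+1050/-1200 mmHg/s, mean transvalvular gradient ~25-35 mmHg, systolic
arterial pressure ~130-140 mmHg with a wide pulse pressure (stiff elderly
arteries):

| parameter | default | unit | note |
|---|---|---|---|
| `emax` | 3.5 | mmHg/ml | end-systolic elastance |
| `emin` | 0.15 | mmHg/ml | diastolic stiffness |
| `v0` | 0 | ml | ESPVR volume intercept (the clinical ESP/ESV ratio convention assumes 0) |
| `t_act`, `t_rel` | 0.27, 0.42 | cycle fraction | double-Hill timing |
| `shape` | (1.9, 14) | — | activation/relaxation exponents; $n_2 = 14$ gives Tau ~37 ms |
| `zc`, `rp`, `c` | 0.06, 1.55, 0.45 | mmHg s/ml, mmHg s/ml, ml/mmHg | Windkessel; $R_pC \approx 0.7$ s reproduces the wide pulse pressure |
| `pven`, `rmv` | 14, 0.03 | mmHg, mmHg s/ml | filling; EDV $\approx$ `pven`/`emin` |
| `eoa`, `k` | 0.7, 44.3 | cm2, ml s$^{-1}$ cm$^{-2}$ mmHg$^{-1/2}$ | severe stenosis; Gorlin constant |

The modeled valve replacement (`applyTavi`) raises EOA (default 1.8 cm2,
dropping the mean gradient below 10 mmHg), scales `emax` by 0.6 (the early
post-procedural contractility drop) and slows relaxation by ~12%
($n_2 / 1.12$). The cohort generator additionally raises the venous
pressure by 1-3 mmHg post-procedure (periprocedural volume/contrast
loading), raises heart rate by 0-30%, and couples the drawn
rapid-ventricular-pacing count to a mild post-procedural arterial
stiffening — a scenario knob that induces a positive association between
pacing burden and the change in Ea without asserting a mechanism.

Cohort draws are uniform over clinically plausible ranges (`cohortDefaults()`):
Ees 1.5-4.8 mmHg/ml, EOA 0.5-0.9 cm2, HR 56-74 bpm, venous pressure 12-16
mmHg, and an elderly arterial tree. 5/8 of patients get the AF label,
3/8 the (placeholder) severe-mitral-insufficiency label.

## The analysis side

### Beat segmentation

Beats are found from dP/dt-max events: local maxima of the smoothed
pressure derivative above 200 mmHg/s with a 0.3 s refractory separation.
The derivative is a central finite difference of a 20 ms moving-average
smoothed pressure — reported dP/dt and Tau use this same smoothed
derivative, so results are reproducible from the documented pipeline. The
beat boundary is end-diastole, located as the onset of the end-diastolic
volume plateau in the 250 ms before the dP/dt-max event: the earliest
sample within 0.5 ml of the window's volume maximum. Taking the earliest
near-maximal sample (rather than the literal argmax) keeps the landmark
from drifting into the pressure upstroke when catheter noise makes the
plateau flat; landmark *values* (EDV/ESV/EDP/ESP) are read from the 20 ms
smoothed channels for the same reason, while stroke work integrates the
raw samples (zero-mean noise cancels in the area).

End-systole is the sample maximizing P/V between the dP/dt extremes — the
clinical ESP/ESV convention with an assumed zero volume intercept.
Intervals are half-open `[start, end)`; indices are 1-based with sample k
at time (k-1)/fs (the R convention, used consistently in files and code).

On noise-free simulated data the detected end-diastole lands within one or
two samples (< 15 ms) of the simulator's pacing clock, and detected ESP
agrees with the true end-systolic pressure to < 1%.

### Extrasystole exclusion and steady state

A beat is flagged when its RR deviates more than 20% (configurable) from
the running median RR; the beat after a *short-coupled* deviant beat — the
post-extrasystolic beat with aberrant loading — is flagged too. Long
deviants (the compensatory pause) do not propagate further, so one
extrasystole produces exactly two flags, matching the simulator's truth
log. The steady-state window is the contiguous run of unflagged beats with
minimal EDV variance (default 10 beats; how many cycles clinical software
averages is not standardized, and 10 is this package's choice). The cohort
builder shortens the window (floor 5 beats, enough for the regressions)
when AF-type irregularity plus the exclusion rule leaves fewer clean beats.

### Indices

Per beat: EDV, ESV, EDP, ESP at the landmarks; SV = EDV - ESV; EF = SV/EDV;
SW as the shoelace area of the closed loop (counterclockwise positive,
magnitude reported, orientation warned about); smoothed dP/dt extremes;
SCI = dP/dt$_{max}$/EDV; Ea = ESP/SV. Two relaxation constants: the
headline `tau_half` is the time for pressure to fall to half its value at
dP/dt-min (the literal half-decay definition, interpolated between
samples); `tau_exp` is the zero-asymptote exponential fit over the window
from dP/dt-min until pressure is within 5 mmHg of the beat's diastolic
floor, provided for comparability with the wider literature. On a true
monoexponential the two stand in the exact relation
`tau_half = ln(2) tau_exp`.

Across beats: PRSW, Ees and Eed are ordinary least-squares slopes of SW on
EDV, ESP on ESV and EDP on EDV over the analyzed window, using the natural
preload variability (no occlusion maneuver is modeled); minimum-spread
guards refuse silent garbage. The per-beat ratio variants (mean ESP/ESV,
mean EDP/EDV) are reported alongside under distinct names because the
ratio-vs-slope convention is genuinely ambiguous in clinical reports.
PRSW from pure preload variation is systematically steeper (~100-150 mmHg
here) than occlusion-derived clinical values (~50-90 mmHg): when preload
alone varies, stroke work gains both width and height with EDV, so the
natural-variability slope approaches ESP rather than the occlusion slope.
Comparisons of PRSW should therefore be within-method, as the pre/post
contrast here is.

The ventricular-arterial coupling ratio is reported in **both**
orientations, explicitly labeled (`vac_ea_ees` = Ea/Ees, `vac_ees_ea` =
Ees/Ea), because clinical usage is split and a silent choice would be
unverifiable. Zva = (systolic arterial pressure + mean gradient)/SVI uses
the recording metadata; missing metadata yields NA with a warning, never a
silent zero.

### The Windkessel closed form for Ea

`windkesselEa` evaluates $E_A = R_T/[t_s + \tau(1-e^{-t_d/\tau})]$ with
$R_T = Z_c + R_p$, systolic/diastolic periods $t_s$, $t_d$, and
$\tau = R_pC$. Two numerical notes: $\tau = 0$ is the analytic limit (the
exponential term vanishes), and as $\tau \to \infty$ the term
$\tau(1-e^{-t_d/\tau}) \to t_d$, so $E_A \to R_T/(t_s+t_d)$ — the factor
$(1-e^{-t_d/\tau})$ alone vanishing does not make the product vanish.

The closed form describes the *arterial* load. Under severe stenosis the
LV-side ESP contains the transvalvular gradient (~25-35 mmHg), which the
arterial formula deliberately excludes, so measured ESP/SV exceeds the
closed form by ~30-40% pre-procedure — a physical property of stenosis,
not an estimator defect. The agreement check (measured Ea within 15% of
the closed form, noise-free) is therefore run on a non-stenotic
configuration (EOA 10 cm2), where it holds with ~10% margin; Ees recovery
is checked on the stenotic default.

## Loop canonicalization and averaging

`canonicalizeLoop` reduces a closed loop polyline to the fixed 40-point
scheme used for loop averaging: four limbs (isovolumic contraction,
ejection, isovolumic relaxation, filling), each resampled to 10 points
equally spaced by arc length in raw (ml, mmHg) coordinates — matching what
a digitizer operator does on a plotted figure, without rescaling. Each
limb includes its starting corner and excludes its ending one, so the 40
points carry no duplicates. Corners: end-diastole is the maximal-volume
vertex (ties within 2% of the volume range — a noisy flat plateau — broken
toward low pressure), end-systole the maximal P/V vertex, and the limb
transitions sit at the last near-extremal-volume vertices between them,
with the same 2% tolerance so flat isovolumic limbs keep their full
extent. `meanLoop` averages corresponding points; it is exact under rigid
translation and idempotent on copies. On simulated beats at 250 Hz the
40-point polygon keeps the dense loop's area to well within 3%.

For schematic mean-loop figures (and the loop-shift check below) loops are
extracted with heavier 40 ms smoothing and up to 10 beats per patient —
presentation-grade averaging of an already-averaged figure, analogous to
digitizing a published mean loop rather than raw catheter sweeps.

## Cohort statistics

Paired pre/post comparisons use the exact Wilcoxon signed-rank test:
zero differences discarded (count reported), tie-averaged ranks, and the
null distribution of W+ enumerated over all $2^n$ sign assignments for
n up to 15; two-sided p is twice the smaller tail, capped at 1. Subgroup
contrasts of per-patient deltas use the exact Mann-Whitney U with the null
enumerated over all assignments of the combined ranks for combined n up to
20. Beyond those sizes both fall back to the tie-corrected normal
approximation (no continuity correction; documented rather than silent).
These enumerations are implemented here because the classical exact
routines decline ties and zeros — at n = 8 precisely the cases that occur —
and the test suite verifies them against independent brute-force oracles
and against `wilcox.test` where the latter is exact.

Kendall's tau-b carries the standard tie corrections in both the estimate
and the variance of S used for the p-value; a constant input makes tau-b
undefined and is flagged as such (estimate NA with a note), never silently
zeroed. Pearson's r uses the t distribution on n-2 df.

Per-patient indices are computed first and cohort tables aggregate
per-patient values (mean of ratios, not ratio of means). No
multiple-testing correction is applied by default — the pilot-style,
exploratory convention — with a Holm option available. The reduced-EF
subgroup threshold defaults to 40% with the alternative 45% split
available as an argument, since both conventions circulate.

The exact paired test at n = 8 is conservative by discreteness: its
empirical type-I error at nominal 0.05 is ~0.04 under a symmetric null
(checked by 10,000-rep simulation in the acceptance suite).

## What the synthetic cohort does and does not show

The generator reproduces: steady-state beats with realistic index values
and beat-to-beat preload variation; AF-type RR irregularity (mild, see
above); short-coupled ectopics with compensatory pauses; catheter-scale
additive noise; and a pre/post contrast whose cohort-level sign pattern —
EF, PRSW, Ees, SW down; Tau, EDP, ESV, EDV up; Ea and Zva roughly stable;
Ees/Ea down — matches what invasive pilot measurements around valve
replacement report. Passing tests on it demonstrates estimator
correctness (parameter recovery, oracle equivalence, calibration), not
clinical validity on real catheter data.

Not modeled (and therefore untested here): baroreflex and autonomic tone,
atrial contraction (no a-wave in the filling limb), regurgitant or
paravalvular leak flow, conductance-catheter calibration drift and
parallel conductance, respiratory modulation, rapid-pacing episodes inside
the analyzed window (representable but excluded by design, as analyses
target pre/post steady states), and any mechanistic link between pacing
burden and afterload beyond the configurable association knob.

## Problem sizes used by the test and acceptance runs

Recovery studies use 20 seeded noise-free 20 s recordings (10-beat
windows); the default cohort is 8 patients x 2 phases x 30 s at 250 Hz;
oracle equivalences use 100 random polygons and 200 random small-sample
test cases; calibration uses 10,000 permutation-null replicates. These
sizes keep every estimator's sampling error far below the asserted bounds
while the whole suite runs in a few minutes on one core.

## A worked run

```{r example, eval = FALSE}
sim <- simulateRecording(duration = 20, fs = 250)
report <- analyzeRecording(sim$recording, n_beats = 10)
report

# ground truth the estimates should recover
truthValues(sim$truth)[c("emax", "tau_ms", "mean_gradient")]

# pre/post cohort and its summary table
ch <- simulateCohort(n_patients = 8, seed = 7)
tb <- buildCohortTables(ch$cohort)
tb$summary
```
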