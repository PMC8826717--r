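---
title: "Model-based patient matching for in-parallel co-ventilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based patient matching for in-parallel co-ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coventr)
```

## The problem

When ventilators are scarce, two patients can be ventilated in parallel from
a single machine ("co-ventilation", Co-MV). In pressure-control (PC) mode
the ventilator imposes a pressure waveform and each patient's tidal volume
(VT) follows passively from their respiratory mechanics. Because the two
patients share one pressure source, a mismatch in mechanics sends one
patient too much air and the other too little; the clinical goal is to keep
both within the lung-protective band of 6–8 mL per kg of body weight.
`coventr` lets a clinician rehearse the whole pairing decision in silico:
which candidate can safely share the index patient's settings, and what
shared setting the pair should then receive.

Both patients must be fully sedated: any spontaneous effort invalidates the
passive models below and the mechanics identification.

## Models

### Single compartment (one patient)

A passive respiratory system on PC ventilation is modelled as one linear
RC compartment,

$$P(t) = E\,V(t) + R\,\dot V(t) + P_0,$$

with airway pressure $P$ (cmH2O), volume above the end-expiratory baseline
$V$ (L), flow $\dot V$ (L/s), respiratory elastance $E$ (cmH2O/L), airway
resistance $R$ (cmH2O·s/L) and baseline pressure $P_0$, taken equal to PEEP
when there is no intrinsic PEEP. The time constant is $\tau = R/E$.

Under an ideal square wave (PIP for $T_i$ seconds, PEEP for $T_e$, period
$T = T_i + T_e = 60/\mathrm{RR}$) the cyclic steady state has the closed
form

$$VT = \frac{\Delta P}{E}\,
  \frac{(1-e^{-T_i/\tau})(1-e^{-T_e/\tau})}{1-e^{-T/\tau}},
  \qquad \Delta P = \mathrm{PIP} - \mathrm{PEEP},$$

implemented in `scm_vt_closed_form()`. The numeric simulator
(`simulate_scm()`, `scm_tidal_volume()`) integrates the same ODE with an
exact exponential step on the zero-order-held pressure; on square waves the
two routes agree to well under 0.1% and the closed form serves as the
analytic oracle for the solver in the test suite, alongside an independent
cross-check against a general-purpose adaptive ODE solver.

$E$ and $R$ are obtained from measured waveforms by ordinary multiple
linear regression of pressure on volume and flow (`identify_mechanics()`),
with the intercept estimating $P_0$ unless it is pinned.

### Double compartment (two patients, one ventilator)

With a second patient in parallel, the shared portion of the circuit adds a
common resistance $R_c$ upstream of the junction. Writing $P_J$ for the
junction pressure,

$$P_J = P_\mathrm{vent} - R_c(\dot V_1 + \dot V_2), \qquad
  P_J = E_i V_i + R_i \dot V_i + P_0 \;(i = 1, 2),$$

so at each instant the two flows solve a 2-by-2 linear system. The package
integrates this first-order state-space form with an exact
matrix-exponential step (`simulate_dcm()`); the equivalent second-order ODE
in the total volume is retained as a verification residual in the property
tests rather than integrated directly, because the state-space form is
numerically robust and extends naturally to more than two compartments.

## The protocol

1. **Validate** the index patient's settings against the safety criteria
   (`validate_settings()`): PPLAT < 35 cmH2O (PIP stands in for PPLAT in PC
   mode — the model has no inspiratory hold, and with zero flow at
   end-inspiration the two coincide), PEEP 5–25 cmH2O, RR 12–20/min, I:E
   1:2–1:5, VT target 6–8 mL/kg. All bounds are inclusive except the
   plateau bound, which is printed as a strict inequality.
2. **Screen** candidates (`screen_candidates()`): each candidate's
   steady-state VT at *their own weight* under the index settings; eligible
   means inside the green 6–8 mL/kg band. `build_re_grid()` draws the same
   information as a map over the whole $(E, R)$ plane (default 1–50 on both
   axes, 200×200 cells) so the clinician sees how much margin a pairing
   has and how the safe region shrinks as weight grows.
3. **Tune** the shared setting for the selected pair (`tune_pip()`): the
   ideal ventilator pressure that would hand each patient exactly their
   single-ventilation VT is
   $P_\mathrm{ideal}(t) = P_\mathrm{square}(t) + R_c(\dot V_1 + \dot V_2)$
   — an "inverse ramp" that overshoots PIP at inspiration onset and can dip
   below zero in expiration, which no real PC ventilator can deliver.
   The inspiratory-phase average of $P_\mathrm{ideal}$ gives the starting
   estimate PIP_EST, and a discrete search in 0.5-cmH2O steps (PEEP, RR and
   I:E held fixed) picks the square-wave PIP minimising the mean of the two
   patients' relative VT errors, capped at the plateau bound.

`run_protocol()` chains all stages and writes the grid, match report,
tuning report and steady-cycle trace as CSV/JSON artifacts; reports are
rounded to reporting precision (0.1 mL, 0.1 cmH2O, 0.01 mL/kg), which also
makes identical configurations byte-identical on disk.

## Worked example

The package ships a six-patient reference cohort (`preset_cohort()`):
index Patient 1 (mild failure, $E=20$, $R=10$, 65 kg, ventilated at
PIP 17 / PEEP 7 / RR 15 / I:E 1:2) and candidates A–E spanning normal,
moderate, mild, obstructive and severe mechanics.

```{r screen}
cohort <- preset_cohort()
settings <- preset_settings()
screen_candidates(cohort$P1, settings, cohort[c("A", "B", "C", "D", "E")])
```

Only Patient C (mild, $E=18$, $R=9$, 80 kg) lands in the green band;
A over-ventilates at 50 kg while B, D and E under-ventilate. Tuning the
selected pair through a shared circuit resistance of 8 cmH2O·s/L:

```{r tune}
circuit <- co_vent_circuit(cohort$P1, cohort$C, Rc = 8)
tuning <- tune_pip(circuit, settings, step = 0.5)
co_mv_report(tuning, circuit)
```

The search settles roughly 6 cmH2O above the single-patient PIP — the
extra driving pressure the shared resistance consumes — and both patients
recover their single-ventilation volumes to about a percent.

A patient whose VT sits *above* the band can be pulled back with an
adjustable resistor in their inspiratory limb; `resistor_adjustment()`
finds the minimal added resistance by bisection (0.01 cmH2O·s/L
resolution). A resistor can only lower VT, so under-ventilated patients
are reported as infeasible rather than given a spurious value.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `Rc` | 8 cmH2O·s/L | added resistance of the shared circuit; a representative value for the lengthened tubing, exposed as configuration |
| `dt` | 0.001 s | integration step; time constants here are 0.3–1.5 s, so 1 ms resolves them to well under 0.5% discretisation error |
| `step` | 0.5 cmH2O | PIP search quantum, the resolution clinicians set PC pressures at |
| steady-state `tol` | 1e-4 | successive-cycle relative VT change declaring cyclic steady state |
| `rise_time` | 0 s | optional linear PEEP-to-PIP ramp at inspiration onset |

Tidal volume is defined at cyclic steady state, not on the first breath
from an empty lung; the two differ by under a percent at the reference
timing but a fixed convention is needed for reproducibility. Reported VT
values therefore assume an ideal square wave; real ventilators apply a
finite pressure rise, which lowers VT slightly — `rise_time` lets users
explore that sensitivity.

## Design choices

- **Exact stepping, not generic solving.** Both models are linear with
  piecewise-constant input, so the per-sample exponential (scalar or
  matrix) update is exact on square waves and unconditionally stable;
  ramps are resolved at $O(dt)$ by the zero-order hold. The recurrences
  run as vectorised recursive filters, so a full tuning pass completes in
  well under a second.
- **PIP_EST averages the inspiratory phase only.** Averaging over the whole
  cycle would mix in the expiratory excursion below PEEP and drag the
  starting point to implausibly low values.
- **The tuning search probes one step downward before ascending.** The
  objective is unimodal in PIP (each patient's VT is increasing in PIP), so
  reporting the discrete argmin is robust regardless of which side of it
  the starting estimate lands on.
- **Both patients' errors are weighted equally** in the tuning objective
  (mean of the two relative VT errors); minimising one patient's error
  alone would silently sacrifice the other.
- **Screening ranks eligible candidates** by closeness to the 7 mL/kg band
  midpoint (ties by elastance similarity to the index patient); eligibility
  itself is the dichotomy that matters, the rank is a convenience ordering.
- **Non-green bands are a reporting convention.** Only the 6–8 mL/kg green
  band is clinically standardised; the yellow/orange grading
  (1-mL/kg steps below, proportional steps above) is configurable in
  `classify_zone()` and carries no decision weight beyond
  eligible/ineligible.

## What the synthetic data does and does not emulate

`random_patient()` / `synthetic_cohort()` draw $E$, $R$ uniformly within
literature-based severity ranges and `noisy_waveform()` adds i.i.d.
Gaussian noise to the pressure channel only, keeping the least-squares
identification unbiased in expectation. Real data differ in ways the
generator deliberately ignores: mechanics drift over time and within
breaths (nonlinear compliance, recruitment), noise also contaminates flow,
spontaneous effort adds unmodelled pressure, and $E$–$R$ pairs correlate
within a patient. Passing tests therefore demonstrate correctness of the
computations on the stated model class, not clinical validity; the method
is a pre-clinical rehearsal tool, and patient state should be re-identified
and the pairing re-checked as disease evolves.

## Numerical conventions and degenerate inputs

Steady state is declared when successive-cycle VT changes by less than
0.01% (both patients, for the coupled model). Phase transitions are
snapped to the nearest sample; at `dt` = 1 ms this is at most 0.5 ms of
timing error. Degenerate cases are typed outcomes, not crashes: empty
candidate lists yield empty reports, a cohort with no green candidate ends
the protocol with a "no-match" report, constant-flow waveforms raise a
non-identifiability error, and a tuning search that hits the plateau cap
returns the best setting found with `cap_reached` set. Repeated equal time
constants in the coupled model (a defective eigensystem) fall back from
the filter-based fast path to plain stepping.

Test and example problem sizes (grid resolutions of 30–60 cells, 100-point
property grids, 20-replicate noise bands frozen from a 200-replicate
calibration) are chosen so the whole suite runs in seconds while leaving
each property's failure modes clearly exposed at much finer resolutions.

## Limitations

- Two patients only, in parallel; in-series circuits and >2-way sharing
  are out of scope.
- Pressure control only — volume-control and any spontaneous-breathing
  mode are excluded by the sedation assumption.
- No oxygenation management: FiO2 cannot be individualised on a shared
  ventilator and is not modelled.
- The per-patient inline resistor is handled as a static screening
  correction, not inside the coupled simulation loop.
- Linear, time-invariant mechanics: no recruitment, no intrinsic-PEEP
  estimation.
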