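---
title: "Lumped-parameter hemodynamics of LVAD cannulation sites: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped-parameter hemodynamics of LVAD cannulation sites: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvadflow)
```

## Scope and idea

`lvadflow` asks a systems-level question: when an extracorporeal left
ventricular assist device (LVAD) returns blood through a femoral versus an
axillary arterial cannula, how does the division of flow among the aortic
branches change, and how disturbed does wall shear become along the aortic
trunk? The package answers it with a transient zero-dimensional
(lumped-parameter) model: the arterial tree is a graph of
resistance–inertance segments, outlets are three-element Windkessels, the
heart is a prescribed pulsatile inflow and the pump a constant-flow graft.
Everything a 3D solver would resolve spatially (jets, secondary flow,
turbulence, wall-normal shear gradients) is deliberately out of scope; what
remains is the network-level redistribution of flow and its signed axial
shear consequences, which is exactly the level at which cannulation-site
comparisons are usually argued.

## Model

**Segments.** Each vessel is a rigid cylinder with Poiseuille resistance
$R = 8\mu l/(\pi r^4)$ and plug-flow inertance $L = \rho l /(\pi r^2)$,
obeying $\Delta P = RQ + L\,\dot Q$. Blood is Newtonian with
$\rho = 1050\ \mathrm{kg/m^3}$ and $\mu = 0.0035$ Pa·s. Rigid walls mean all
compliance is lumped at the outlets; this mirrors the common rigid-lumen CFD
assumption and makes the cycle-mean behaviour exactly that of a resistive
network (the test suite exploits this with an independent Ohmic oracle).

**Outlets.** A three-element Windkessel $(R_p, C, R_d)$ with venous
reference $P_v$ closes every outlet. The chamber ODE
$C\,\dot P_c = Q - (P_c - P_v)/R_d$ is discretised by backward Euler, which
for the current state reduces algebraically to an affine interface relation
$P = aQ + b$ with $a = R_p + R_d\,\Delta t/(R_d C + \Delta t)$. Each outlet
contributes this relation to the nodal system, so the 0D boundary is coupled
implicitly ("tightly") within a single linear solve per step — no operator
splitting, no stability constraint from the boundary. A loose-coupling
validation mode (`solver_settings(coupling = "subiteration")`) instead
iterates the pressure/flow exchange to a normalised residual of $10^{-4}$
and is required by the tests to agree with the monolithic path.

**Sources.** The cardiac inlet prescribes a half-sine ejection over a
systolic fraction of the cycle with an optional brief reverse notch at valve
closure and zero diastolic flow; the peak is solved in closed form so the
cycle mean is exact. The LVAD is a constant-flow injection through a short
graft stub (30 mm, 2.5 mm radius) attached one segment proximal to the
cannulated artery's own outlet, so the cannulated artery keeps its
Windkessel and its own share can still be reported.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| Cardiac period $T$ | 0.8 s (75 bpm) | typical resting rate; configurable |
| Systolic fraction | 0.375 | physiological ejection duration |
| Notch fraction / depth | 0.05 / 0.1 | brief valve-closure backflow |
| Cardiac output | 5 L/min | normal adult resting value |
| Pressure targets | 120/80 mmHg | textbook brachial/aortic reference |
| $P_v$ | 0 mmHg | standard Windkessel practice; only pressure differences drive splits |
| $\Delta t$ | 1 ms | resolves the waveform; backward Euler is unconditionally stable |
| Cycles | 3, final cycle analysed | start-up transient is small (see below) |
| $R_p : (R_p+R_d)$, $\kappa$ | 0.06 | see "Proximal resistance fraction" |
| $\tau_{wk} = R_d C$ (initial) | 1.5 s | typical arterial washout time constant |
| Scenario set | baseline, FA40, FA60, AA40, AA60 | heart+pump always total 5 L/min (3+2, 2+3) |

The geometry is a literature-typical adult aortic tree (ascending aorta
12.5 mm radius tapering to 7 mm infrarenally; 3.5–4.5 mm arch branches;
4 mm femorals; 30 segments in all), not a patient anatomy. Only relative
redistribution between scenarios and the qualitative shear behaviour are
claimed; every length and radius is overridable through the configuration.

## Calibration

`initial_params_from_shares()` sizes each outlet Ohmically: the total path
resistance to an outlet with target share $s_i$ at mean pressure MAP is
$(\mathrm{MAP}-P_v)/(s_i\,\mathrm{CO})$, minus the upstream Poiseuille path
(clamped at a small positive floor), split $\kappa$ / $1-\kappa$ into
$R_p$ / $R_d$, with $C_i = \tau_{wk}/R_{d,i}$. `calibrate_windkessel()` then
iterates: run three cycles, measure achieved shares and inlet
systolic/diastolic pressure, update $R_{d,i}$ multiplicatively by the
achieved/target share ratio, rescale all resistances by the MAP ratio and
all compliances by the pulse-pressure ratio. With the default network this
converges in about five evaluations to share errors below 0.01 pp and
pressures within 2 mmHg. The calibrated table is then frozen — an immutable
view that errors on any mutation attempt — and reused verbatim in every LVAD
scenario, so all between-scenario differences are attributable to the
cannulation site alone.

**Proximal resistance fraction.** $\kappa$ approximates the ratio of the
vessel's characteristic impedance to its total peripheral resistance,
typically 5–10%. In this network the segments carry explicit inertance, and
the inertial contribution to systolic pressure (~10 mmHg at the default
waveform) adds to the $R_p Q$ pulse. At $\kappa \approx 0.09$ those two
contributions alone exceed a 40 mmHg pulse pressure, leaving the compliance
update no room to calibrate; the default $\kappa = 0.06$ keeps the proximal
pulse near 24 mmHg so that 120/80 mmHg is attainable with a finite, stable
compliance.

**Pressure readings.** Systolic pressure is the final-cycle maximum at the
inlet. Diastolic pressure is the minimum over the diastolic phase, i.e.
after the ejection and notch windows of the inlet waveform. A rigid-segment
network exaggerates the end-systolic incisura (there is no proximal wall
compliance to absorb the ejection deceleration), and counting that brief
undershoot as "diastolic" would make textbook pulse pressures unreachable;
`inlet_pressures()` documents this choice.

## Numerical choices and degenerate inputs

* Backward Euler everywhere (segments and chambers): first-order, A-stable,
  and exact in the DC limit. Halving $\Delta t$ moves cycle-averaged outlet
  flows by <0.5% and per-segment TAWSS by ~0.1%.
* Chamber pressures are initialised at the steady operating point of the
  cycle-mean inflows (solved on the resistive network), so the start-up
  transient is small and three cycles suffice for a periodic solution
  (cycle-to-cycle outlet-flow change ≈ 0.02%, gate at 1%).
* The final-cycle analysis window is the last $T/\Delta t$ steps; all cycle
  averages are trapezoidal.
* OSI is $0/0$ for identically zero shear; the package defines it as 0 (no
  oscillation). `TAWSS = 0` therefore implies `OSI = 0`.
* Percentages are rendered half-away-from-zero at one decimal. Rendered
  share columns are reconciled by largest remainder so each column sums to
  exactly 100.0, matching the reference table's convention; variations are
  rounded from unrounded differences (which is why a rendered share pair can
  show a 0.1 discrepancy against its own variation cell, as reference tables
  of this kind also do).
* The end-systolic split `end_systolic_split()` defaults to the end of the
  systolic fraction — the close of ejection. At that instant cardiac inflow
  is zero by construction, so for pump-supported runs the default reports a
  0/100 split; the instant is configurable because there is no canonical
  definition, and no numeric agreement with any particular published split
  is claimed. With zero total instantaneous inflow the split is undefined
  and raised as an error.
* Degenerate inputs: zero mean flow gives the identically zero waveform; a
  zero-flow network yields all-zero TAWSS/OSI; single-cycle runs still
  produce tables with the periodicity diagnostic flagged `NA`/not-ok;
  empty parameter sets cannot be frozen.

## What the synthetic tree does and does not emulate

The generator reproduces the *structure* of the clinical comparison: one
inlet, fifteen named branch outlets with graftable right-axillary and
right-femoral sites, baseline flow divisions taken from the bundled
reference table, 40%/60% pump-support scenarios at a constant 5 L/min total.
It does not reproduce patient anatomy, 3D jet impingement at the cannula,
turbulence, or wall compliance. Two consequences matter when reading
results. First, because branch outlet impedances (~10⁹ Pa·s/m³) dwarf the
vascular path resistances (~10⁶–10⁷), share *variations* between scenarios
are an order of magnitude smaller than a patient-specific 3D model produces;
the package therefore asserts only their direction and ordering (femoral
perturbs more than axillary; the cannulated artery gains), never their
magnitude. Second, trunk shear metrics use the Poiseuille closure on bulk
flow, so TAWSS levels are low-biased relative to 3D near-wall values; the
package's shear claims are bound-type (femoral-60 thoracic TAWSS below
1 Pa, axillary trunk OSI at most 0.2) and contrasts, both of which the
reduced model reproduces robustly: with femoral support the
thoraco-abdominal trunk truly reverses every cycle (OSI up to ~0.5), while
axillary support keeps trunk flow unidirectional (OSI ≈ 0).

## Problem sizes

The shipped configuration is 30 segments / 31 nodes / 15 outlets, 800 steps
per cycle, three cycles per run; a full calibration plus five scenarios
takes a few seconds on one CPU, and the whole test suite (which re-runs the
study plus some forty additional simulations) finishes in well under a
minute. These sizes are the study conditions, chosen to match the modelled
physiology — not a computational ceiling.

## Known limitations

* No pump pressure–flow characteristic: the LVAD is an ideal flow source,
  so heart–pump flow competition is not modelled.
* No baroreflex or peripheral autoregulation: Windkessel parameters are
  frozen across scenarios by design.
* Signed scalar shear only; transverse WSS and relative residence time have
  no 0D counterpart.
* The inertial incisura artefact discussed above; pressure waveform *shape*
  should not be over-interpreted.
* Single synthetic anatomy; no inter-patient variability.
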