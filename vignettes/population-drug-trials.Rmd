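---
title: "Simulating hiPSC-CM populations and in silico drug trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hiPSC-CM populations and in silico drug trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Human induced pluripotent stem cell-derived cardiomyocytes (hiPSC-CMs) beat
spontaneously, are immature relative to adult ventricular myocytes, and are
the workhorse of contemporary in vitro cardiac safety screening. This package
implements the in silico counterpart of such a screen: a Hodgkin-Huxley-type
ordinary-differential-equation model of a ventricular-like hiPSC-CM, tools to
extract the action-potential (AP) and Ca2+-transient (CaTr) biomarkers used
by optical recording platforms, a population-of-models workflow calibrated
against experimental biomarker ranges, and pore-block drug trials with
rule-based classification of arrhythmic phenotypes.

## The cell model

The membrane equation is

$$C\,\frac{dV}{dt} = -(I_{Na} + I_{NaL} + I_f + I_{CaL} + I_{to} + I_{Kr} +
I_{Ks} + I_{K1} + I_{NCX} + I_{NaK} + I_{pCa} + I_{bNa} + I_{bCa} -
I_{stim}),$$

with two compartments (cytosol and sarcoplasmic reticulum). The SR exchanges
Ca2+ with the cytosol through a RyR release flux with activation,
inactivation and Ca-dependent adaptation gates, a SERCA uptake pump and a
passive leak; cytosolic and SR Ca2+ use instantaneous buffering. Automaticity
is carried by the funny current and by diastolic SR Ca2+ release, which
depolarizes the membrane through the forward mode of the Na+/Ca2+ exchanger:
just before the upstroke, I_NCX contributes about -0.5 A/F on top of roughly
-0.25 A/F of I_f. As a consequence, blocking I_NCX slows and - above ~90%
block - abolishes spontaneous activity, which is the behaviour that motivated
the revised fast-Na+ formulation: the I_Na window current is small, so the
cell cannot sustain pacemaking from I_Na alone.

Internal units are seconds, volts (the state vector) and A/F; user-facing
traces carry Vm in mV, and reported biomarkers use ms, mV, V/s and nM.

### Parameter provenance and verification

The packaged baseline (`inst/extdata/model_parameters.yaml`) is a
reconstruction of the revised model: the predecessor model's equation set
with the updated I_Na and I_f formulations, and constants verified against
the published steady-state behaviour of the revised cell at 37 degrees C
(spontaneous cycle length 1712 ms, APD30 224 ms, MDP -74.9 mV, APA 102 mV,
CaTr amplitude ~160 nM, pre-upstroke I_NCX/I_f levels, and the I_NCX-block
and cooling experiments). Two design choices were resolved by that
verification:

* the I_Na inactivation steady state uses the square-root sigmoid
  $h_\infty = (1 + e^{(V + 72.1)/5.7})^{-1/2}$ of the model family's earlier
  published form; the plain sigmoid alternative produced upstroke velocities
  roughly 2.3-fold too low;
* the SR uptake/release constants (V_up, K_up, the RyR adaptation time
  constant) were fixed at the values that jointly reproduce the published
  cycle length and Ca-transient amplitude.

Residual deviations of the frozen baseline from the published steady-state
row are APD90 +4%, maximal upstroke velocity within ~8% (and grid-dependent),
and CaTr decay time -10%; these are the honest limits of the reconstruction
and are asserted - and partially fail - at their stated 2% tolerance in the
acceptance tests rather than being loosened.

### Temperature and concentration adaptation

`adapt_to_environment()` matches the simulation to the recording conditions:
the thermodynamic temperature enters every Nernst potential and the explicit
temperature terms of I_NCX/I_NaK via RT/F, extracellular Na+/K+/Ca2+ are
replaced, and every gating time constant in family $i$ is multiplied by
$Q_{10,i}^{(37 - T)/10}$, so cooling slows kinetics. The Q10 table is part of
the editable parameter file; in the packaged default every gating family
(I_Na, I_NaL, I_CaL, I_Kr, I_Ks, I_to, I_f, I_rel) uses 2.1 and the pumps
are not rescaled beyond their explicit temperature terms - a conventional
channel-gating value adopted because the source values for each family are
not recoverable from the main text of the underlying study. Cooling the
baseline from 37 to 21 degrees C (with Nao 135, Ko 5.4, Cao 1.33 mM)
roughly doubles the spontaneous cycle length and prolongs APD90 to ~1.1 s,
inside every experimental bound of the packaged range table.

## Simulation protocols and numerics

The stiff ODE system is integrated with `deSolve::lsoda` over a C
implementation of the right-hand side, with relative tolerance 1e-7 and
per-state absolute tolerances scaled to each state's magnitude (both
configurable; a 10x refinement moves steady-state biomarkers by well under
0.5 ms). Paced protocols restart the solver at every stimulus edge so the
rectangular pulse is never stepped over. The stimulus is a 5 ms rectangular
pulse of 10 A/F - about twice the diastolic threshold determined by
bisection on the baseline; a much larger pulse would ride the artifact above
the AP peak and corrupt amplitude-referenced durations.

Steady-state runs integrate 800 s and biomarkers average the last 20 beats.
Traces keep a trailing window (300 s by default) at full sampling resolution
(1-5 ms); earlier output is thinned to bound memory. The window covers 21
beats for cycle lengths up to ~14 s, beyond the slowest accepted cell.
Upstroke velocity is reported from the sampled derivative channel (computed
exactly from the currents at each sample, not by finite differences);
densely sampled output (0.25 ms) is used where dV/dt_max itself is the
quantity of interest.

## Biomarkers

Beats are segmented MDP-to-MDP around each detected activation (the argmax
of dV/dt within a suprathreshold excursion; excursions peaking below -40 mV
are not upstrokes). Durations APDx run from the activation to the first
downward crossing of peak - x% of amplitude, with amplitude referenced to
the beat's own following MDP and all crossings found by linear
interpolation - exact on piecewise-linear test fixtures. The triangulation
ratio is (t40 - t30)/(t80 - t70). A repolarization that never reaches its
90% level yields an absent value (never NaN arithmetic), which downstream
calibration rejects cleanly.

For the Ca2+ transient, the diastolic level is the pre-peak minimum within
the beat window and the onset is the foot of the rapid rise,
operationalized as the last upward crossing of diastolic + 10% amplitude
before the peak. The model's diastolic Ca2+ exhibits a slow pre-release
creep (it is part of the automaticity mechanism), so anchoring the onset at
the raw diastolic minimum would fold several hundred milliseconds of quiet
diastole into the rise time; the foot convention reproduces the published
~690 ms transient duration and ~180 ms rise-to-peak at 37 degrees C, and
keeps all rise times inside the experimental bounds. CTDx run from this
onset to the decay crossing of peak - x% amplitude; AP cycle length is
measured between consecutive activations and CaTr cycle length between
consecutive onsets.

## Population calibration

`sample_scalings()` draws 22 dimensionless multipliers per candidate -
thirteen maximal conductances/fluxes (I_Na, I_NaL, I_f, I_CaL, I_to, I_Ks,
I_Kr, I_K1, I_NCX, I_NaK, I_pCa, I_rel, I_up), the activation and
inactivation time constants of I_Na, I_CaL and I_rel, the I_rel adaptation
time constant and half-inactivation Ca2+ level, and the SERCA
half-saturation K_up - by Latin hypercube sampling, uniform on 50-200% of
baseline. Each member is simulated 800 s nonpaced and 800 s paced at 0.5 Hz
from the packaged adapted steady state, and is accepted when every
mode-relevant biomarker mean lies within the experimental [LB, UB] bounds:
nonpaced cycle lengths, durations, triangulations and rise time; the same
minus cycle lengths when paced; plus - in AP-containing modes - a nonpaced
AP peak inside [17.0, 57.7] mV, the published surrogate for the amplitude
information optical dyes cannot provide. Three calibration modes (AP_only,
CaTr_only, AP_CaTr) mirror the study design; the combined mode is by
construction the intersection of the other two.

The packaged range table stores the published optical-recording bounds
verbatim. Its upper bound is computed as max(mean + 2 SD): the source prints
"max(mean - 2 SD)", which cannot exceed its own lower bound on any single
sample and is treated as a typographical slip (a config switch restores the
literal reading). Members whose paced run does not capture 1:1 (paced cycle
length != 2000 ms) are rejected with a distinct reason, as are quiescent and
solver-failed candidates; both denominators are reported.

Problem sizes are deliberately desk-scale: the test suite calibrates 100
candidates and the acceptance script 60, against 30,000 in the original
study. At these sizes the acceptance pattern (CaTr_only > AP_only > AP_CaTr,
with a combined acceptance fraction of roughly 1-2%) is reproduced; the
absolute accepted counts of the full-scale study are a cluster-scale
computation and are not asserted.

## Drug trials

Drugs act by simple pore block: each targeted current's maximal conductance
is multiplied by $1/(1 + ([D]/IC_{50})^h)$. The packaged IC50/Hill/dose
files are synthetic reconstructions (so marked in their filenames and
headers): the study's own table lives in supplementary material that is not
redistributed here, so the files were assembled from the anchors printed in
the main text - bepridil leaves exactly 32% residual I_CaL at 10 uM,
dofetilide's top in vitro dose blocks ~80% of I_Kr, astemizole's and
diltiazem's top doses are 0.1 and 10 uM - completed with literature-typical
patch-clamp potencies. They are inputs, not code: replacing them with the
original table requires no source change.

Trials integrate 400 s nonpaced from each member's control steady state.
The classifier implements the study's rules verbatim: EADs are extra peaks
above -55 mV between consecutive upstrokes (with a 1 mV prominence floor
against solver ripple); repolarization failure is a stable (max |dV/dt| <
0.1 V/s) potential above -40 mV over the last 15 s; irregular rhythm is a
consecutive cycle-length change greater than 150%; residual activity means
excursion peaks between -40 and 0 mV; quiescence an average potential below
-40 mV over the last 15 s with no suprathreshold peaks. Because the
published category table is exclusive but silent on conflicts, the primary
label follows the fixed precedence RA > Q > RESAC > IRR > OK (a
repolarization abnormality is the safety-relevant event); all detector
outputs are kept on the label object for audit, including the tachycardia
flag (spontaneous rate above 2 Hz over the final 30 s).

The drug-direction checks run on a scaled-down trial population: the
baseline plus two dozen candidates sampled at 60-165% of baseline and
screened against the nonpaced experimental ranges. That narrower range
trades the full population's diversity for runtime while still containing
weak-repolarization-reserve members, which is what the
EAD-provocation experiment needs: members that are EAD-free under bepridil
(whose I_CaL block partially offsets its I_Kr block) develop EADs once the
I_CaL component of the block is halved or removed.

## Synthetic fixtures

`make_synthetic_trace()` builds piecewise-linear AP/CaTr templates with
plantable abnormalities. Piecewise-linear shapes are chosen precisely so
every amplitude-referenced crossing has a closed form, making the analysis
pipeline testable to interpolation exactness (1e-9 s) without the solver.
The fixtures emulate morphology only: they contain no optical noise,
photobleaching, motion artifacts or syncytial averaging, so passing
fixture tests demonstrates correctness of the measurement and classification
logic, not robustness to raw optical data. One convention is inherently
grid-quantized: the activation anchor (argmax of dV/dt) can sit one sample
off the analytic upstroke foot, so absolute APDx values on fixtures are
asserted to one record step while all crossing-to-crossing quantities are
asserted to 1e-9 s.

## Known limitations

* The baseline constants are a verified reconstruction, not the authors'
  published table; APD90, dV/dt_max and the CaTr decay time carry the
  residuals listed above.
* Single cells only: no tissue or syncytium, hence none of the damping that
  makes multicellular preparations less arrhythmic than isolated models, and
  no simulated tachyarrhythmias.
* Ventricular-like phenotype only; no atrial- or nodal-like variants.
* The drug tables are reconstructions; quantitative per-dose abnormality
  counts should not be compared against the original study's table beyond
  direction and ordering.
* Pore block only: no state-dependent or kinetic drug binding.
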