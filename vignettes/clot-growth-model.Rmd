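---
title: "A coupled flow–coagulation–platelet model of clot growth under arterial shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled flow-coagulation-platelet model of clot growth under arterial shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clotsim` models clot formation on a collagen + tissue-factor (TF) patch in
a rectangular microfluidic channel perfused with whole blood at an arterial
wall shear rate, together with the measurement-processing and statistical
pipeline used to analyse such assays. This vignette is the package's own
account of the model: the governing equations and their assumptions, the
parameters that matter and why their defaults are what they are, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The physical model

### Geometry and flow

The domain is a 2-D channel cross-section, 600 µm long and 60 µm high
(the out-of-plane 250-µm width only enters flux conversions), with a
thrombogenic patch of 20 or 100 µm centred at x = 300 µm on the bottom
wall. Blood is treated as a Newtonian fluid (µ = 3.5 mPa·s,
ρ = 1060 kg/m³). The channel Reynolds number at the 10 mm/s mean velocity
is ~10⁻², so the steady *Stokes* equations are solved; an optional Picard
iteration on the lagged advective term confirms that including inertia
changes the solution by well under 1%.

The growing clot acts on the fluid through a linear Brinkman drag
−µ·k·**u**, where the viscous resistance k (1/m², the inverse
permeability) is assembled per cell from the bound-platelet volume
fraction φ_b and the fibrin-derived volume fraction φ_f by the
Kozeny–Carman relation

k(φ; d) = 180 φ² / ((1 − φ)³ d²),

with grain diameters d = 2 µm for packed platelets and 0.1 µm for fibrin
fibres, and φ_f = 1.5·10⁻⁷ per nM of fibrin. At φ_b = 0.3 the platelet
term alone is ~1.2·10¹³ m⁻², giving a Brinkman screening length below a
micron — flow inside a mature clot is effectively stagnant, which is what
produces the sharp low-velocity boundary around the deposition domain.

The inlet drives the target wall shear directly: a plane-Poiseuille
profile u(y) = γ̇·y·(1 − y/h) with γ̇ = 1000 s⁻¹, mean velocity
γ̇h/6 = 10 mm/s. The device's total flow rate and its 8-channel
pressure-relief split are not modelled; the wall shear rate is taken as
the authoritative boundary condition because it is what the biology sees.

### Coagulation network

Nine plasma proteins and their complexes are tracked as concentration
fields (nM): FVII/FVIIa, FIX/FIXa, FX/FXa, FVIII/FVIIIa, FV/FVa,
prothrombin/thrombin, fibrinogen/fibrin, TFPI and its FXa complex, plus
the tenase (FIXa:FVIIIa) and prothrombinase (FXa:FVa) assemblies. The
rate laws are mass action and Michaelis–Menten with literature-scale
constants of the Hockin–Mann lineage, stored as plain data in
`coagulation_network()` so any entry can be overridden. Plasma baselines
(FII 1400, FX 170, FIX 90, FVII 10, FVIII 0.7, FV 20, fibrinogen 9000,
TFPI 2.5 nM) describe an average healthy subject; FVIIa circulates at 1%
of FVII. The contact (FXII) pathway is deliberately absent — the assays
this model represents inhibit it with corn trypsin inhibitor.

Surface chemistry lives on the thrombogenic faces: TF sites (0.1 or
2 molecules/µm², i.e. 1.66·10⁻¹³ or 3.32·10⁻¹² mol/m²) capture both
plasma FVIIa *and* zymogen FVII. Capture of the zymogen is included
because surface-bound FVII is autoactivated by neighbouring TF:FVIIa fast
compared with the capture step; with the 0.1 nM plasma FVIIa alone the TF
loading time constant would be ~435 s — longer than the whole experiment —
whereas the 10 nM FVII pool loads the surface in seconds, so the response
is controlled by the amount of TF rather than by an arbitrary loading lag.
TF:FVIIa then activates FIX and FX into the wall-adjacent fluid, and the
TFPI:FXa complex quenches it irreversibly.

Complex assembly (tenase, prothrombinase) and fibrin polymerisation are
*gated* by local platelet availability: their rates scale with
min(φ_b/0.05, 1) and vanish in platelet-free plasma. Procoagulant
phospholipid surface is supplied by deposited platelets; gating localises
thrombin amplification and fibrin to the clot, which is what produces the
fibrin-rich core nested inside the platelet shell. Without it (or with
even a 1% plasma leak) fibrin accumulates in the thrombin plume far
outside the platelet domain and the core/shell architecture is lost.

One consequence worth knowing: the initial surface FXa pulse is quenched
by TFPI before enough platelets have deposited to support amplification,
so domain-integrated free thrombin shows a small early hump (a few per
cent of its final value) before the main burst. Bound platelets and
fibrin, which cannot leave the domain, are strictly monotone.

### Platelets

Four phenotype fields: mobile resting/activated (number densities,
platelets/µL; inlet 2.5·10⁵/µL with 0.5% circulating activated) and bound
resting/activated (immobile volume fractions, capped at φ_max = 0.6).

*Margination.* Red cells expel platelets toward the walls. The model is a
conserved enhancement profile: density in a 5-µm layer at either wall is
3× the bulk, applied as a per-column multiplicative reweighting that
conserves each column's platelet count exactly and reduces to the
identity for a flat profile.

*Capture.* Mobile platelets are captured at first order onto thrombogenic
faces (adhesion) and onto cells in contact with bound-activated clot
(aggregation), with the saturation factor (1 − φ/φ_max) and conversion
between counts and volume through the 11-fL platelet volume. Resting
platelets are captured at 30% of the activated efficiency (their
GPIb/vWF-mediated capture is weaker than integrin-mediated aggregate
growth). The base capture/contact rate is 0.065 s⁻¹ and the single
calibration knob — a platelet adhesion-rate multiplier with
post-calibration value 4 — scales it, mirroring the one-parameter
calibration such models undergo against platelet-deposition data. The
base rate was fixed once, by order-of-magnitude analysis of the capture
flux (enhanced near-wall density × platelet volume × saturation) followed
by coarse calibration runs against reported model clot heights
(~24 µm for the long/high-TF condition, 16–19 µm elsewhere at 400 s), and
is not revisited.

*Activation.* Thrombin activates platelets at rate
k_act·T/(EC50 + T) with EC50 = 1 nM and k_act = 0.5 s⁻¹ at saturation.
Bound resting platelets in contact with an activating surface — the
collagen faces, or cells whose neighbourhood already holds activated
bound platelets — additionally convert at a fixed contact rate
(0.065 s⁻¹). Extending contact activation from the collagen strip to the
clot surface is a deliberate design choice: it represents
contact-dependent activation (collagen, ADP/TxA2 signalling at the
aggregate surface) and lets the deposition domain propagate in the low-TF
conditions, where free thrombin stays in the sub-nanomolar range for most
of the run yet platelet clots demonstrably grow. Without it, growth
stalls at a few microns whenever the thrombin burst is weak.

No shedding or embolisation term is included: the bound-platelet domain
grows monotonically.

## Numerics

* **Flow.** Finite-volume MAC (staggered) discretisation; the coupled
  (u, v, p) saddle-point system is solved by a sparse direct LU after
  row/column equilibration (momentum coefficients ~µ/Δx² ≈ 10⁹ dwarf the
  continuity rows; without equilibration the factorisation loses the
  divergence constraint). Every continuity equation is retained — the
  outlet-face momentum pins the pressure level — so the discrete
  divergence and the inlet/outlet flux balance hold to ~10⁻¹⁴. No-slip
  walls use a quadratic ghost, making the solver exact for parabolic
  profiles.
* **Species transport.** Implicit-upwind ADI (Lie-split finite-volume)
  sweeps per species: unconditionally stable, mass-conservative,
  non-negativity preserving (M-matrix). The transport time through the
  domain (~60 ms) is far below the 0.5-s coupling step, so each implicit
  step effectively relaxes the fields to their quasi-steady balance,
  which is the physically correct regime. Fibrin is polymer and is not
  transported.
* **Reactions.** Per-cell adaptive Heun integration with an embedded
  Euler/Heun error estimate (relative tolerance 10⁻⁴ per sub-step);
  chemically inert cells are skipped. Against an independent stiff
  (`deSolve::lsoda`) integration of the same rate table the trajectories
  agree to better than 0.1%.
* **Coupling.** Transport and platelet steps advance every 0.5 s; the
  flow field is re-solved every 10 s of simulated time. The resistance
  field evolves on tens of seconds (a cell needs ~30 s of capture to
  change k appreciably), so a faster flow cadence changes nothing but the
  run time; the cadence is a config key.
* **Problem sizes.** The desk-scale default is the 2-µm grid
  (300 × 30 cells), which runs one 450-s condition in about a minute; a
  1-µm preset exists for long runs. Halving Δx moves the 400-s platelet
  total by under 10% on the default; contour heights move by at most one
  coarse cell.
* **Degenerate inputs.** Zero TF density means zero surface flux (an
  inert run, not an error); an all-zero profile is an error for edge
  detection but merely "empty" for contour extraction; ties in the
  largest-component rule resolve to the first-found component (stable
  given the deterministic scan order); the packing cap is enforced by
  proportional scaling inside a capture sub-step so φ never exceeds
  φ_max.

Core and shell contours are thresholded fields (1 nM fibrin; 5% of φ_max
for platelets — the deposition boundary is quantified rather than judged
by eye, and the threshold is a config key). Because both are thresholded
on the same grid, the fibrin fringe can top the shell contour by a
boundary cell; `core_shell_pair(clip = TRUE)` clips the core to the shell
when pairing simulated contours, and the embedding operation preserves
nesting by construction.

## The synthetic-data generator

No experimental data ship with the package; `generate_profiles()` and
`generate_kinetics()` produce datasets with the statistical structure the
analysis chain assumes, so every stage can be tested against known ground
truth:

* deposition profiles: a squared-cosine bump per donor (5) × repetition
  (4), centred at 300 µm plus a normal jitter (SD 15 µm, the unregistered
  camera frame), peak height drawn from a lognormal donor effect
  (CV 25%, shared across a donor's repetitions) around the
  condition mean — 7.5 µm for short/low, 13–16 µm for the others —
  growing monotonically in time, with additive noise and, with small
  probability, a spurious secondary bump;
* kinetics: saturating-growth curves per analyte whose plateaus encode
  the condition ordering and a 20-fold thrombin/fibrin ratio between the
  combined and reference conditions, with lognormal donor scatter and
  multiplicative measurement noise.

Profiles are generated in height-equivalent units so they are directly
comparable to simulated domain heights; an arbitrary-unit scale is applied
afterwards where normalisation is being exercised.

What passing the pipeline tests on these data shows: the alignment,
filtering, averaging and statistical routing recover known centres,
peaks, spurious labels and group differences at the stated rates. What it
does not show: that real fluorescence backgrounds, bleaching, optical
registration errors or donor pathology behave like the generator's noise
model — the generator emulates the *structure* the pipeline assumes, not
microscopy physics.

One statistical caveat surfaced by the generator: pooling donors'
repetitions into one sample (as the analysis chain does) makes
observations within a condition share the donor effect. With a realistic
donor CV the pooled two-sample comparisons are anticonservative; the
generator's type-I calibration test therefore switches the donor effect
off, and real-data users should read the pooled p-values with that in
mind.

## Known limitations

* 2-D: out-of-plane flow and wall effects of the 250-µm width are absent.
* Continuum platelets: no discrete aggregates, no GPIb/vWF bond mechanics
  (these enter only through the calibrated capture rate), no clot
  viscoelasticity or embolisation.
* The reaction table is a reduced TF-pathway set with literature-scale
  constants; absolute thrombin levels in the weak-trigger conditions are
  more uncertain than the strong-trigger ones, and inter-condition
  contrasts should be read as order-of-magnitude statements.
* Quasi-steady flow coupling and the margination reweighting both assume
  their processes are fast compared with clot growth; at much higher
  occlusivity than simulated here (shell heights ≤ ~40% of the channel)
  those assumptions would need revisiting.
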