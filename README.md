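# clotsim

Blood clots growing under arterial shear both obstruct and are shaped by
the flow around them. `clotsim` simulates this feedback in a 2-D
microfluidic channel (60 µm high, 250 µm wide) in which whole blood at a
wall shear rate of 1000 s⁻¹ meets a collagen + tissue-factor (TF) patch on
the bottom wall — 20 µm ("short") or 100 µm ("long") long, patterned at
~0.1 ("low") or ~2 ("high") TF molecules/µm². It is aimed at researchers
studying thrombosis under flow who want a tested, desk-scale model of the
coupled system and of the measurement pipeline used to analyse such assays.

The model couples:

* **Flow** — steady incompressible Stokes flow with a Brinkman momentum
  sink −μ·k·**u** representing the porous clot; k (1/m²) is the viscous
  resistance, the inverse permeability, obtained from the local
  platelet/fibrin composition by a Kozeny–Carman law
  k(φ; d) = 180 φ² / ((1−φ)³ d²).
* **Coagulation biochemistry** — reaction–convection–diffusion transport of
  the TF-pathway network (factors II, V, VII, VIII, IX, X, fibrinogen,
  TFPI, and their active forms and complexes), triggered by surface TF that
  captures plasma FVII/FVIIa and activates FIX and FX; thrombin (FIIa)
  converts fibrinogen to fibrin. Red cells enter implicitly through the
  shear-enhanced diffusivity D_eff = D_b + k_sh·a²·γ̇·H·(1−H)^0.8.
* **Platelets** — four phenotype fields (mobile/bound × resting/activated)
  with near-wall margination, first-order adhesion/aggregation capture that
  saturates at a packing cap, and thrombin-driven Hill-type activation.

Downstream of the simulator, the package implements the full analysis
chain: clot **core** extraction (1-nM fibrin contour) and **shell**
extraction (5% of the platelet packing cap), rescaled-core embedding into
measured shells, flow through measured clot shapes, fluorescence
deposition-profile processing (width-averaged profile alignment to 300 µm,
spurious-profile filtering, mean ± SD bands), the
Jarque–Bera/t/rank-sum/Bonferroni group-comparison pipeline, and a
synthetic microfluidic data generator (5 donors × 4 repetitions per
condition) so every stage is testable without experimental data.

## Worked example

Simulate the long-surface/high-TF condition on the desk-scale 2-µm mesh to
450 s (about a minute of wall time):

```r
library(clotsim)
cfg <- simulation_config("long_hi", t_end = 450, snapshot_times = 400)
sim <- simulate_clot_growth(cfg)
sim
#> Clot-growth simulation [long_hi]: 450 s on 300 x 30 cells
#>   final totals: platelet 622 um^2, thrombin 4.18e+04 nM um^2, fibrin 9.02e+07 nM um^2
```

`platelet` is the integrated bound-platelet area (µm² of platelet material
per µm of channel width), `thrombin`/`fibrin` are domain integrals
(nM·µm²). `summary()` adds the clot geometry at the 400-s snapshot:

```r
summary(sim)
#> Condition: long_hi
#> Shell peak height 22.0 um (occlusivity 0.37), core peak height 26.0 um
#>  time_s   platelet     thrombin       fibrin
#>       0   0.000000     0.000000 0.000000e+00
#>      50   9.923814     3.046984 5.397265e+02
#>     ...
#>     400 438.640963 18659.827594 3.104973e+07
#>     450 622.271081 41845.898748 9.016088e+07
```

The shell (platelet deposition domain) peaks at 22 µm — about a third of
the channel height — while the other three conditions stay in the 14–20 µm
band: clot height is robust to TF localisation even though thrombin and
fibrin outputs vary by orders of magnitude. The underlying flow solve is
conservative to machine precision:

```r
st <- solve_flow(sim$mesh, fluid_properties())
st
#> Stokes-Brinkman flow: 300 x 30 cells, Q_in = 6.003e-07 m^2/s, mass error 1.11e-14, max |div| 5.86e-11
```

Comparing conditions takes one call per run plus `synergy_ratio()`:

```r
runs <- lapply(setNames(nm = canonical_conditions()$condition), function(cc)
  simulate_clot_growth(simulation_config(cc, t_end = 450, snapshot_times = 400)))
synergy_ratio(runs, "thrombin", t = 450)$fold   # >> 20
```

Increasing surface length (5×) and TF density (20×) together multiplies
the available TF 100-fold, and the cascade amplifies this into a far more
than 20-fold increase in thrombin and fibrin at 450 s — the combined
effect is strongly super-additive, while each single factor alone has a
moderate effect.

The vignette (`vignettes/clot-growth-model.Rmd`) documents the model,
its parameters and the synthetic-data generator in detail.

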