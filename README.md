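# perfustim

A desk-scale digital twin of a perfusion bioreactor with capacitively
coupled electric-field stimulation, for model-driven design of osteogenic
cell-culture microenvironments.

Tissue-engineering bioreactors deliver two physical stimuli to
cell-seeded scaffolds: fluid-induced wall shear stress from perfusing
culture medium, and low-magnitude electric fields delivered through
insulated (capacitive) electrodes. Whether the dose inside the scaffold
actually falls in the osteoinductive windows reported for mesenchymal
stromal cells — shear stress τ ∈ [1.47, 24] mPa or [0.20, 13.35] mPa,
field magnitude |E| ∈ [10⁻⁵, 1.3·10³] V/m — cannot be measured at
culture scale; it must be predicted by physics models and spot-validated
against bench-measurable quantities. `perfustim` implements that whole
workflow for R users:

* **Geometry**: parametric voxel generators for an orthogonal woodpile
  scaffold (10.0 × 10.0 × 2.75 mm, 500 µm filament/pore, 10%
  superposition), a honeycomb scaffold (10.2 × 10.2 × 3.0 mm, 250 µm
  truss, 300 µm macropore), simplified scaffold holders
  (horizontal/vertical), ITO-PET electrode assemblies and a plate
  validation cell; STL/VTK export.
* **Hydraulics**: the lumped Poiseuille manifold with the
  area-conservation rule (child areas sum to the parent's at every
  split), which preserves mean velocity and splits 50 mL/min into exact
  quarters: v = Q/A = 0.328 m/s at the hose connector.
* **Flow physics**: a MAC staggered-grid Stokes solver
  (−µ∇²u + ∇p = 0, ∇·u = 0) with no-slip solids and pressure openings;
  shear rate γ̇ = √(2 D:D), wall shear τ = µγ̇, and a Reynolds
  diagnostic.
* **Field physics**: a quasistatic frequency-domain solver
  ∇·(σ*∇V) = 0 with complex admittivity σ* = σ + iωε₀εᵣ, lumped or
  resolved thin PET films, a 1D layered-media analytic oracle,
  series-resistor and current-to-field corrections.
* **Dose analysis**: volume-weighted ROI histograms normalized to peak,
  in-window volume fractions, and linear protocol rescaling.
* **Design loop**: scores all scaffold × holder × protocol hypotheses
  and selects the fabrication candidate with an auditable rationale
  trace, plus the prediction-vs-measurement validation arithmetic.

## Worked example

Predict the microenvironment of the bench validation cell and the
selected chamber design:

```r
library(perfustim)

# 1D layered oracle: PET film | 10 mm medium | PET film at 5 V, 60 kHz
o <- layered_1d_oracle(list(list(thickness = 175e-6, material = "PET"),
                            list(thickness = 10e-3,  material = "medium"),
                            list(thickness = 175e-6, material = "PET")),
                       V_amp = 5, f = 60e3)
o$E_mag[2]
#> [1] 0.09536798

# the 3D solver on the voxelized validation cell agrees
g   <- build_validation_cell(gap = 10e-3, resolution = 0.5e-3)
sol <- solve_em(g, em_bc(V_amp = 5, f = 60e3))
mean(sol$E_mag[label_mask(g, "medium")])
#> [1] 0.09536798

# back-calculate the field from the measured bench current
field_from_measured_current(E_pred = 0.095, I_pred = 3.21e-5, I_meas = 2.43e-5)
#> [1] 0.07191589

# chamber prediction for the selected design (minutes on one CPU)
asm  <- assemble_chamber(scaffold_spec("orthogonal"), "horizontal",
                         electrodes = electrode_assembly(gap = 22e-3),
                         spacing = 200e-6)
sole <- solve_em(asm, em_bc(V_amp = 5, f = 60e3), tol = 1e-6)
roi_histogram(sole$E_mag, extract_roi(asm), asm)$mean
#> [1] 0.1094398
```

The first number is the uniform field predicted between the validation
electrodes (≈0.095 V/m — almost the entire 5 V drop sits across the PET
films, so the medium field is small and independent of the gap); the
last is the ROI-average |E| over the scaffold envelope of the selected
design, where the insulating filaments squeeze the current paths and
raise the average above the open-cell value.

## Analysis workflow

The study itself lives in `analysis/` as numbered drivers that write
tables under `results/`:

1. `01_hydraulics.R` — manifold rule and flow budget
2. `02_geometry.R` — scaffold voxelization, solid fractions, STL/VTK
3. `03_flow_microenvironment.R` — shear histograms for all four designs
4. `04_field_microenvironment.R` — field histograms on the horizontal holder
5. `05_design_loop.R` — the decision loop and design report
6. `06_validation.R` — prediction-vs-measurement arithmetic

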