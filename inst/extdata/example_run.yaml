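# Example run configuration: the baseline chamber field study.
# Lengths accept explicit unit suffixes (um / mm / cm / m); everything is
# stored and computed in SI.
scaffold:
  kind: orthogonal
  envelope: [10.0mm, 10.0mm, 2.75mm]
  filament: 500um
  pore: 500um
  superposition: 0.10
holder: horizontal
electrodes:
  gap: 22mm
  plate_size: [33mm, 18mm]
  pet_thickness: 175um
protocol:
  pump_flow_mL_min: 50
  V_amp: 5
  frequency_Hz: 60000
solver:
  em_spacing: 200um
  flow_spacing: 400um
  em_tol: 1.0e-6
  flow_tol: 1.0e-6
seed: 1
out_dir: results
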