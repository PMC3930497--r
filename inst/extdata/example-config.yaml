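# Example rbdna configuration: 1-um DNA in 100 mM salt, hat-curve protocol.
units:
  b_nm: 3.4
  bp_per_cylinder: 10
  temperature_K: 298.15
dna:
  persistence_length_nm: 50
  twist_persistence_length_nm: 95
  salt_mM: 100
  n_cylinders: 300
  anchor: weld
  bead: true
  bead_radius_nm: 50
solver:
  erp: 0.8
  cfm: 1.0e-10
  sor_relaxation: 1.3
  sor_iterations: 64
thermostat:
  mode: global
  gamma: 10
integrator:
  dt: 0.000592
  n_steps: 1.0e6
  output_stride: 100
experiment:
  mode: hat-curve
  force_pN: 1
  turns: [-20, -10, 0, 10, 20]
  equil_steps: 2.0e5
  sample_steps: 5.0e5
  ramp_rate: 0.05
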