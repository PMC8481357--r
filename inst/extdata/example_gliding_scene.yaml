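drop_radius_um: 18.0
nu_m2_s: 1.0e-06
rho_kg_m3: 1000.0
depth_scale_um: 1.0
seed: .na
bodies:
- shape: capsule
  x_um: -8.2
  y_um: -1.2
  dims_um:
  - 6.7
  - 0.716
  orientation_rad: 0.0
  vx_um_s: 2.0
  vy_um_s: 0.0
- shape: capsule
  x_um: -8.2
  y_um: 1.2
  dims_um:
  - 6.7
  - 0.716
  orientation_rad: 0.0
  vx_um_s: 2.0
  vy_um_s: 0.0
- shape: capsule
  x_um: 0.0
  y_um: 0.0
  dims_um:
  - 6.7
  - 0.716
  orientation_rad: 0.0
  vx_um_s: 2.0
  vy_um_s: 0.0
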