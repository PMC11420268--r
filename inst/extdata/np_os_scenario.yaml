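name: np_os
anatomy:
  chamber_radii:
  - 30.0
  - 26.0
  - 24.0
  pv_dirs:
  - - 0.300165136249901
    - 0.250137613541585
    - 0.920506417833031
  - - 0.601687089090165
    - 0.62174332539317
    - -0.501405907575137
  - - -0.621119022268167
    - 0.420758047342952
    - 0.66119121725321
  - - -0.70175658996392
    - 0.551380177828794
    - -0.451129236405377
  pv_radius: 6.0
  pv_length: 30.0
  mv_dir:
  - 0.100180487462608
  - -0.901624387163469
  - -0.420758047342952
  mv_radius: 12.5
  mv_length: 10.0
  laa_dir:
  - 0.899640215856101
  - -0.119952028780813
  - 0.419832100732847
  laa_ostium_diameter: 24.0
  laa_depth: 34.0
  laa_taper: 0.675
  wall_resolution: 2.0
device:
  family: non_pacifier
  nominal_size: 27.0
  deployed_diameter: 24.0
  body_length: 23.0
  disc_thickness: ~
  cove_radius: 3.5
  cove_depth: 2.5
  shoulder_radius: 2.0
  insert_radius: 3.0
  insert_height: 2.5
placement:
  depth_offset: 0.0
  tilt: 0.0
  tilt_toward: mv
  lateral_offset: 0.0
  lateral_toward: mv
fluid:
  density: 1060.0
  viscosity: 0.0035
waveform:
  period: 1.01
  s_amp: 0.36
  s_phase: 0.13
  s_width: 0.2
  d_amp: 0.45
  d_phase: 0.55
  d_width: 0.28
  baseline: 0.09
  per_pv_scale:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
roi_diameter: 40.0

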