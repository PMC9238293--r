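anatomy:
  layers:
  - name: skin
    thickness: 1.1
  - name: subcutaneous fat
    thickness: 13.0
  - name: muscle
    thickness: 42.0
  fill: soft tissue
  lateral_extent: 300.0
  vertical_extent: 200.0
  depth_extent: 100.0
  spacing: 2.0
  spine:
    enabled: no
    vertebra: 10.0
    epidural_fat: 2.2
    csf: 2.9
    cord_radius: 1.9
    center_x: 0.0
    start_depth: 58.9
sources:
  actuators:
    centers:
    - - 60.0
      - 16.0
    - - 60.0
      - -16.0
    - - -60.0
      - 16.0
    - - -60.0
      - -16.0
    radius: 22.5
    temperature: 45.0
  mat_temperature: 40.0
  mat_half_width: .inf
  convection:
    h: 5.0
    T_amb: 25.0
  cut_temperature: 37.0
solver:
  tolerance: 1.0e-08
  max_iterations: 20000.0
circulation:
  form: logistic
  baseline_temperature: 37.0
  fit_baseline_temperature: 34.9
  calibration: builtin
sweep:
  temperatures:
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
profiles:
  actuator_anchor:
  - 60.0
  - 16.0
  depths:
  - 2.0
  - 4.0
  - 6.0
  - 8.0
  - 10.0
  - 12.0
  - 14.0
  - 16.0
  - 18.0
  - 20.0
  - 22.0
  - 24.0
  - 26.0
  - 28.0
  - 30.0
  - 32.0
  - 34.0
  - 36.0
  - 38.0
  - 40.0
  lateral_depths:
  - 20.0
  - 30.0
  lateral_x:
  - -140.0
  - -138.0
  - -136.0
  - -134.0
  - -132.0
  - -130.0
  - -128.0
  - -126.0
  - -124.0
  - -122.0
  - -120.0
  - -118.0
  - -116.0
  - -114.0
  - -112.0
  - -110.0
  - -108.0
  - -106.0
  - -104.0
  - -102.0
  - -100.0
  - -98.0
  - -96.0
  - -94.0
  - -92.0
  - -90.0
  - -88.0
  - -86.0
  - -84.0
  - -82.0
  - -80.0
  - -78.0
  - -76.0
  - -74.0
  - -72.0
  - -70.0
  - -68.0
  - -66.0
  - -64.0
  - -62.0
  - -60.0
  - -58.0
  - -56.0
  - -54.0
  - -52.0
  - -50.0
  - -48.0
  - -46.0
  - -44.0
  - -42.0
  - -40.0
  - -38.0
  - -36.0
  - -34.0
  - -32.0
  - -30.0
  - -28.0
  - -26.0
  - -24.0
  - -22.0
  - -20.0
  - -18.0
  - -16.0
  - -14.0
  - -12.0
  - -10.0
  - -8.0
  - -6.0
  - -4.0
  - -2.0
  - 0.0
  - 2.0
  - 4.0
  - 6.0
  - 8.0
  - 10.0
  - 12.0
  - 14.0
  - 16.0
  - 18.0
  - 20.0
  - 22.0
  - 24.0
  - 26.0
  - 28.0
  - 30.0
  - 32.0
  - 34.0
  - 36.0
  - 38.0
  - 40.0
  - 42.0
  - 44.0
  - 46.0
  - 48.0
  - 50.0
  - 52.0
  - 54.0
  - 56.0
  - 58.0
  - 60.0
  - 62.0
  - 64.0
  - 66.0
  - 68.0
  - 70.0
  - 72.0
  - 74.0
  - 76.0
  - 78.0
  - 80.0
  - 82.0
  - 84.0
  - 86.0
  - 88.0
  - 90.0
  - 92.0
  - 94.0
  - 96.0
  - 98.0
  - 100.0
  - 102.0
  - 104.0
  - 106.0
  - 108.0
  - 110.0
  - 112.0
  - 114.0
  - 116.0
  - 118.0
  - 120.0
  - 122.0
  - 124.0
  - 126.0
  - 128.0
  - 130.0
  - 132.0
  - 134.0
  - 136.0
  - 138.0
  - 140.0
outputs:
  directory: results
  formats:
  - csv
  - vtk
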