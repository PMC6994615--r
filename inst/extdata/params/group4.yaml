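group: 4
segmentation:
  gradient_band_weights:
  - 0.3
  - 0.3
  - 0.4
  region_growing_band_weights:
  - 0.3
  - 0.3
  - 0.4
  priority_function:
  - 0.0
  - 0.1
  - 0.15
  - 0.2
  - 0.3
  - 0.5
  - 1.0
  competition_threshold: 0.02
merging:
  mean_difference:
  - - 0.05
    - 1.0
    - 2.0
  - - 0.1
    - 1.5
    - 2.5
  - - 0.15
    - 1.8
    - 3.0
  - - 0.2
    - 2.0
    - 3.2
  std_difference:
  - - 0.0
    - 1.0
    - 0.2
  - - 0.008
    - 1.5
    - 0.4
  - - 0.015
    - 1.8
    - 0.6
  - - 0.02
    - 2.0
    - 0.75
  band_weights:
  - 0.3
  - 0.3
  - 0.4
  maximum_area: 50000.0
  small_segment_area: 500.0
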