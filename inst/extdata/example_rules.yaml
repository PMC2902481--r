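# Segmentation rules matched to default_phantom_spec(); windows are
# intensities, sizes mm^2, offsets/boxes mm relative to the named structure.
spine:
  intensity_window: [700, 900]
  size_window: [250, 500]
  reliability_rank: 1
mandible:
  intensity_window: [850, 1050]
  size_window: [100, 1400]
  reliability_rank: 2
  location_prior:
    ref: spine
    offset: [0, -75, 40]
    box: [20, 25, 25]
hyoid:
  intensity_window: [550, 750]
  size_window: [40, 200]
  reliability_rank: 3
  location_prior:
    ref: mandible
    offset: [0, 2, -32]
    box: [15, 15, 14]
jugular_left:
  intensity_window: [150, 270]
  size_window: [60, 150]
  reliability_rank: 4
  location_prior:
    ref: hyoid
    offset: [-28, 32, 0]
    box: [10, 10, 60]
jugular_right:
  intensity_window: [150, 270]
  size_window: [60, 150]
  reliability_rank: 5
  location_prior:
    ref: hyoid
    offset: [28, 32, 0]
    box: [10, 10, 60]
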