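# Example dropscreen pipeline configuration.
# Seeds are mandatory for `simulate`; every block is optional and falls back
# to the package defaults (the canonical 154-anchor chip).
seed: 42
layout:
  n_anchors: 154
  chamber_area_mm2: 200      # 2 cm^2 trapping chamber
  pitch_um: 1000
  anchor_radius_um: 250
  pixel_size_um: 10
codebook: default            # or a path to a codebook CSV
timepoints_h: [24, 144]
growth:
  d0_um: 80
  dmax_um: 250
  rate_per_h: 0.05
  sdlog: 0.08
optics:
  noise_sd: 6
  background_level: 100
segmentation:
  min_area_um2: 1000
  max_area_um2: 200000
  min_circularity: 0.6
window_radius: 5             # px, barcode read window
p_empty: 0                   # probability an anchor trapped no cell droplet
immune_arm: false            # true enables the CFSE exclusion rule in `score`
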