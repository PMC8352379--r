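# Default pipeline configuration: simulate the full eight-group design
# (4 wavelengths x {GNR, saline}, 4 animals/group) and analyze it end to end.
simulate: true
exposure_s: 90
effective_roi_pixels: 1
roi_diameter_px: 30
alpha: 0.05
seed: 1
camera:
  frame_rate: 6
  width: 160
  height: 120
  noise_sd: 0.7
  quantization_step: 0.01
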