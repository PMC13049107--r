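# Demo pipeline configuration: simulate a thorax phantom, calibrate the
# water/aluminum LUTs, run the segmentation-based correction, evaluate.
seed: 7
setup:
  kvp: 70
  prefiltration_mm_al: 2.5
  energy_min: 10
  energy_max: 70
  energy_step: 0.5
  v0_model:
    v_max: 0.35
    design_energy_kev: 27
    slope_per_kev: 0.02
  c_d: 1
  pixel_size_mm: 0.4
weights:
  sex: male
phantom:
  shape: [256, 256]
  d_true: 0.6
normalizer: mask_area
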