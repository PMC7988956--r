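# Shared configuration of the analysis run: a 43-specimen synthetic cohort
# processed at 0.3 mm voxel and reference-grid resolution.
seed: 7
out_dir: results/run
synth:
  n_specimens: 43
  voxel_size: 0.3
  noise_sd: 60
density:
  grid_spacing: 0.3
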