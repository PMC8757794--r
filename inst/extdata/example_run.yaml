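# Example fdbraid run configuration. Paths are relative to the working
# directory; 'device' may be a preset name (Derivo, P64, Pipeline,
# Surpass) or a device JSON file.
vessel: example_centerline.csv
device: Pipeline
output_dir: fdbraid_out
deployment:
  n_theta: 16
  distal_s: 2
region:
  s_start: 18
  s_end: 24
generate:
  n: 64
phantom:
  noise_sd: 0.02
  threshold: 0.1
seed: 1
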