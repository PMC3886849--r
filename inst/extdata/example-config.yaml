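# Example gliaquant pipeline configuration.
# Omitted keys keep package defaults (17 H-I animals + 17 twin controls,
# triplicate 512x512 8-bit sections per marker).
seed: 42
image_width: 256
image_height: 256
n_sections: 3
skip_images: false
write_images: false
cohort:
  n_hi: 17
  n_week1: 10
  necrosis_gain: 30
  jitter_sd: 0.02
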