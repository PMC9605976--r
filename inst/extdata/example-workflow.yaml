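# Example configuration for run_workflow() / inst/cli/eggchamber.R:
# generate a wild-type cohort of 126 egg chambers.
command: generate
seed: 0
out: eggchamber-out/wt
generator:
  genotype: wt
  n_chambers: 126
  noise_cv: 0.05
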