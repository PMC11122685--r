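# Reduced-size pipeline configuration for a quick demonstration run.
# Entries merge over default_pipeline_config(); anything omitted keeps its
# default (notably the WT/mutant system contrasts).
seed: 853
enm:
  n_residues: 20
  n_frames: 150
two_state:
  n_frames: 50000
eda:
  n_frames: 20
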