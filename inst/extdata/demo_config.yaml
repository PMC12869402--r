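# Demo configuration for runPipeline(): a reduced synthetic study.
seed: 1
population:
  nPerClass: 6
  nNonselective: 4
tubularity:
  n_boot: 300
alignment:
  dsa_restarts: 5
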