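# Demo pipeline configuration: small synthetic paired cohort.
seed: 1
output_dir: iedburden_demo
simulate:
  n_subjects: 3
  duration: 300
  between_sd: 0.3
  within_sd: 0.2
endpoints:
  - burden
  - spindle_all
  - spindle_fast
  - spindle_slow
annotate:
  n_ieds: 15
  background_s: 12
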