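# Demo pipeline configuration (synthetic cohort, small sizes).
# Run with: run_pipeline(system.file("extdata", "demo-config.yaml", package = "pvahmm"))
# after editing out_dir, or copy and adapt.
out_dir: pvahmm-demo
seed: 1
window_minutes: 15
K: 4
k_folds: 5
n_patients: 10
n_windows: 150
n_restarts: 3
lambda: [1, 11, 38, 119]
stationary: [0.52, 0.28, 0.14, 0.06]
persistence: 0.85
exposure_rate: 330
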