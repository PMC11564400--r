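# Demo configuration for run_pipeline() / inst/scripts/twinpath.R:
# simulates a cohort whose true cross-lags are zero but whose cross-time
# genetic and shared-environment correlations are not, then runs the full
# analysis ladder.
seed: 1
data:
  simulate:
    traits: [cd, pb]
    n_mz: 800
    n_dz: 800
    crosslag: {f: 0.0, g: 0.0}
    crosstime: {h1: 0.25, h2: 0.25, j1: 0.35, j2: 0.35}
    missing_rate: 0.05
preprocess:
  standardize: [cd_t1, cd_t2, pb_t1, pb_t2]
models:
  saturated: [cd_t1, pb_t1]
  ace: [cd_t1, pb_t1]
  crosslag: {x: cd, y: pb}
inference:
  alpha: 0.05
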