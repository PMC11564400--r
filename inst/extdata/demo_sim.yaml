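# Demo simulate config (fields of sim_config); used as
#   Rscript inst/scripts/twinpath.R simulate --config demo_sim.yaml --out cohort.csv
traits: [cd, pb]
n_mz: 500
n_dz: 500
crosslag: {f: 0.0, g: 0.0}
crosstime: {h1: 0.25, h2: 0.25, j1: 0.35, j2: 0.35}
pgs: {p1: 0.15, p2: 0.05}
missing_rate: 0.1
seed: 7
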