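# Example ggflux pipeline configuration (built-in toy model).
# Run with:  run_pipeline(system.file("extdata/example-config.yaml", package = "ggflux"))
photon_bound: 100
cleavage_mode: both
supply: exchange
strains: [WT, dggpS, dglpK]
reference: dslr1670
seed: 1
out_dir: ggflux-run
sweep_grid: [0.0001, 0.001, 0.01, 0.1, 1.0, 1.5]
intervals:
  - {t0: 0, t1: 2, qGG: 0.008}
  - {t0: 2, t1: 4, qGG: 0.015}
  - {t0: 4, t1: 6, qGG: 0.014}
  - {t0: 6, t1: 8, qGG: 0.009}
  - {t0: 8, t1: 10, qGG: 0.003}
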