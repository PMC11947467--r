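# Low-density synthetic scratch assay (density-independent truth) and a
# short exponential-submodel refit of the written data.
seed: 1
synth:
  scenario: scratch
  replicates: 11
  noise: 20
fit:
  data: observations.csv     # written by the synth stage into out_dir
  geometry: cartesian1d
  model: exponential
  mcmc: {walkers: 12, steps: 60, burnin: 0.5, refine_maxit: 50}
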