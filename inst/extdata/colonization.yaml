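# Barrier-release colonization simulation (1-D, posterior-mode parameters)
# plus the traveling-wave analytics for the same parameter set.
seed: 1
simulate:
  params: {D: 1300, k1: 0.612, k2: 0.457, K1: 4965, K2: 5435}
  crowding: {f: linear, g: linear}
  grid: {geometry: cartesian1d, L: 3000, "N": 300}
  initial: {rho1: 4800, rho2: 0, step_at: 850}
  times: {from: 0, to: 24, by: 6}
  report: {threshold: 50}
wave:
  params: {D: 1300, k1: 0.612, k2: 0.457, K1: 4965, K2: 5435}
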