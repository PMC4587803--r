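# Configuration stub for the 39-parameter NF-kB signalling model.
#
# The model equations, parameter values, initial conditions and the
# catalogue of published experiments are NOT bundled with this package:
# they live in the supplementary material of the original modelling
# literature. This stub documents the schema; fill in `rhs`, `parameters`,
# `initial` and the experiment list from that material to run the full
# pathway analysis (clustering, identifiability, screening) exactly as for
# the bundled fixtures. Loading the stub as-is fails with a diagnostic
# because the state equations are empty.
schema: micca/1
model:
  name: nfkb
  states: [y1, y2, y3, y4, y5, y6, y7, y8, y9, y10,
           y11, y12, y13, y14, y15, y16, y17, y18, y19]
  parameters: {}     # 39 kinetic parameters, e.g. {ka: ..., KN: ..., ki: ...}
  rhs: {}            # one expression per state, e.g.
                     #   y1: "ka * y16 * (KN - y1) * ka20 / (ka20 + y9) - ki * y1"
  initial: {}
  inputs:
    tnf: {type: piecewise_linear, times: [0, 600, 3600, 4200], values: [0, 1, 1, 0]}
experiments: []      # published protocols: observed species, times, perturbations
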