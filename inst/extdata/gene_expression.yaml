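# Two-state gene expression model: mRNA produced at rate kr and degraded at
# rate gr; protein translated at rate kp and degraded at rate gp.
# Identical to the built-in gene_expression fixture.
schema: micca/1
model:
  name: gene_expression
  states: [r, p]
  parameters: {kr: 1.0, kp: 1.0, gr: 2.0, gp: 0.3}
  rhs:
    r: "kr - gr * r"
    p: "kp * r - gp * p"
  initial: {r: 0, p: 0}
  steady_state:
    r: "kr / gr"
    p: "kr * kp / (gr * gp)"
experiments:
  - name: steady_state
    observe: [r, p]
    times: [100]
    steady_state: true
  - name: decay
    observe: [r, p]
    times: {from: 0.05, to: 20, length: 24, spacing: log}
    initial: {r: 10, p: 20}
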