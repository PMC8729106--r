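inputs:
- species: A
  profile: constant
  amplitude: 100.0
  baseline: 0.0
  phase: 0.0
  duty: 0.5
- species: R0
  profile: constant
  amplitude: 100.0
  baseline: 0.0
  phase: 0.0
  duty: 0.5
genes:
- product: R1
  logic: single
  bindings:
  - tf: A
    lambda0: 2.0e-06
    mu: 0.0002
    role: activator
  - tf: R0
    lambda0: 0.001
    mu: 0.01
    role: repressor
  nu: 0.02
  delta: 0.0001
  fixed_delay_steps: 0
  init: 0.0
  init_on: no
- product: R2
  logic: single
  bindings:
  - tf: A
    lambda0: 2.0e-06
    mu: 0.0002
    role: activator
  - tf: R1
    lambda0: 0.001
    mu: 0.01
    role: repressor
  nu: 0.02
  delta: 0.0001
  fixed_delay_steps: 0
  init: 0.0
  init_on: no
- product: R3
  logic: single
  bindings:
  - tf: A
    lambda0: 2.0e-06
    mu: 0.0002
    role: activator
  - tf: R2
    lambda0: 0.001
    mu: 0.01
    role: repressor
  nu: 0.02
  delta: 0.0001
  fixed_delay_steps: 0
  init: 0.0
  init_on: no
- product: R4
  logic: single
  bindings:
  - tf: A
    lambda0: 2.0e-06
    mu: 0.0002
    role: activator
  - tf: R3
    lambda0: 0.001
    mu: 0.01
    role: repressor
  nu: 0.02
  delta: 0.0001
  fixed_delay_steps: 0
  init: 0.0
  init_on: no
reactions: []

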