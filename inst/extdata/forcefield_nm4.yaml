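bead_types:
- W
- Q0
- Qa
- Na
- C
repulsion:
- - 100.0
  - 98.0
  - 98.0
  - 102.0
  - 130.0
- - 98.0
  - 110.0
  - 100.0
  - 102.0
  - 130.0
- - 98.0
  - 100.0
  - 110.0
  - 102.0
  - 130.0
- - 102.0
  - 102.0
  - 102.0
  - 100.0
  - 110.0
- - 130.0
  - 130.0
  - 130.0
  - 110.0
  - 100.0
friction:
- - 4.5
  - 4.5
  - 4.5
  - 4.5
  - 20.0
- - 4.5
  - 9.0
  - 4.5
  - 4.5
  - 20.0
- - 4.5
  - 4.5
  - 9.0
  - 4.5
  - 20.0
- - 4.5
  - 4.5
  - 4.5
  - 4.5
  - 9.0
- - 20.0
  - 20.0
  - 20.0
  - 9.0
  - 4.5
temperature: 1.0
units:
  r0_nm: 0.71
  tau_ps: 143.0
  kBT_ref: 1.0
  Nm: 4
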