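goal: US driving risk factors 2019
criteria:
  - id: C1
    label: Environment
    evidence_group: environment
    factors:
      R1: Weather
      R2: Light
      R3: Road design
      R4: Control device
  - id: C2
    label: Driver state
    evidence_group: driver_state
    factors:
      R5: DUI
      R6: Non-performance errors
  - id: C3
    label: Driver behavior
    evidence_group: driver_behavior
    factors:
      R7: Decision errors
      R8: Performance errors
      R9: Recognition errors
criteria_pcm:
  labels: [C1, C2, C3]
  entries:
    - ["1", "1/4", "1/5"]
    - ["4", "1", "1"]
    - ["5", "1", "1"]
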