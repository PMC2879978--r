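{
  "ipr": 0.059,
  "dr": 0.093,
  "icr_phase1": 0.765,
  "outcome_phase1": 0.592,
  "di_phase1": 0.032,
  "spr": 0.088,
  "cir": 0.914,
  "icr_phase2": 0.457,
  "outcome_phase2": 0.467,
  "di_phase2": 0.008,
  "scr": 0.778,
  "n_eligible": 32878
}
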