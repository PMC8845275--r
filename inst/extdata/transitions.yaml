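# Microvascular stage-transition tables: ordered forward chains with
# annual probabilities per adjacent stage pair, multiplied by
# hba1c_rr^(HbA1c - 7). Simplified stand-in sub-models (editable data)
# ensuring every chronic health state in the utility and cost catalogs is
# reachable; amputation enters through its own event equation.
retinopathy:
  states: [none, bdr, pdr, svl]
  p: [0.040, 0.015, 0.020]
  hba1c_rr: 1.15
nephropathy:
  states: [none, microalbuminuria, gross_proteinuria, esrd_hemodialysis, esrd_peritoneal, esrd_transplant]
  p: [0.020, 0.015, 0.010, 0.020, 0.020]
  hba1c_rr: 1.20
macular_edema:
  states: [none, macular_edema]
  p: [0.006]
  hba1c_rr: 1.15
cataract:
  states: [none, cataract]
  p: [0.012]
  hba1c_rr: 1.05
neuropathy:
  states: [none, neuropathy]
  p: [0.020]
  hba1c_rr: 1.15
foot:
  states: [none, active_ulcer, healed_ulcer, amputated]
  p: [0.005, 0.50, 0.0]
  hba1c_rr: 1.20
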