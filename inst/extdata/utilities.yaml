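# Health-state utilities and event-based disutilities (EQ-5D-preferring
# literature values). States combine additively: each active state
# subtracts (baseline - state utility) from the no-complication baseline.
baseline_utility: 0.785
state_utilities:
  post_mi: 0.730
  angina: 0.695
  chf: 0.677
  post_stroke: 0.621
  pvd: 0.724
  microalbuminuria: 0.785
  gross_proteinuria: 0.737
  hemodialysis: 0.621
  peritoneal_dialysis: 0.581
  renal_transplant: 0.762
  bdr: 0.745
  pdr: 0.715
  svl: 0.711
  macular_edema: 0.745
  cataract: 0.769
  neuropathy: 0.701
  active_ulcer: 0.615
  healed_ulcer: 0.785
  post_amputation: 0.505
event_disutilities:
  mi: -0.055
  stroke: -0.164
  amputation: -0.280
hypo_disutilities:
  nonsevere_daytime: -0.004
  nonsevere_nocturnal: -0.007
  severe_daytime: -0.057
  severe_nocturnal: -0.062
bmi_disutility_per_unit: -0.0061
bmi_reference: 25
hypo_model: evans
alternatives:
  # alternative BMI slope (flatter weight-utility gradient)
  lee_bmi_per_unit: -0.0038
  # alternative constant hypoglycemia decrements
  currie:
    nonsevere_daytime: -0.0035
    nonsevere_nocturnal: -0.0035
    severe_daytime: -0.047
    severe_nocturnal: -0.047
  # diminishing model: the i-th lifetime event of a severity class carries
  # decrement d * ratio^(i - 1)
  lauridsen_ratio: 0.8
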