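{
  "n_patients": 40,
  "ecog_probs": {"0": 0.63, "1": 0.37},
  "group_log_mean_steps": {"0": 8.856946, "1": 8.59508},
  "between_patient_sd": 0.45,
  "nb_dispersion": 6,
  "treatment_day_effect": 0.5,
  "recovery_days": 3,
  "symptom_coupling": -1.0,
  "improvement_prob_base": 0.3,
  "improvement_coupling": 2.5,
  "improvement_shift": -2.0,
  "wear_prob_start": [0.92, 0.99],
  "wear_decay_per_day": 0.15,
  "wear_logit_sd": 3.5,
  "partial_day_prob": 0.02,
  "msas_cutpoints": [0.4, 2.2, 3.8, 5.2],
  "msas_patient_sd": 0.8,
  "psych_item_offset": 1.2,
  "sigma_method": "relative"
}
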