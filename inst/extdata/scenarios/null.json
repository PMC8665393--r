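{
  "n_patients": 27,
  "ecog_probs": {"0": 0.5, "1": 0.5},
  "group_log_mean_steps": {"0": 8.699515, "1": 8.699515},
  "between_patient_sd": 0.45,
  "nb_dispersion": 6,
  "treatment_day_effect": 1.0,
  "recovery_days": 0,
  "symptom_coupling": 0.0,
  "improvement_prob_base": 0.6,
  "improvement_coupling": 0.0,
  "improvement_shift": -1.0,
  "wear_prob_start": [1.0, 1.0],
  "wear_decay_per_day": 0.0,
  "wear_logit_sd": 0,
  "partial_day_prob": 0.0,
  "msas_cutpoints": [0.4, 2.2, 3.8, 5.2],
  "msas_patient_sd": 0.8,
  "psych_item_offset": 1.2,
  "sigma_method": "relative"
}
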