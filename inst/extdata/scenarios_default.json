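[
  {"name": "Time horizon down to 1 y",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 12}]},
  {"name": "Time horizon down to 3 y",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 36}]},
  {"name": "Time horizon up to 7 y",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 84}]},
  {"name": "Discount rate down to 0%",
   "edits": [{"path": "discount.annual_rate", "op": "set", "value": 0}]},
  {"name": "Discount rate up to 10%",
   "edits": [{"path": "discount.annual_rate", "op": "set", "value": 0.10}]},
  {"name": "Intervention costs halved",
   "edits": [{"path": "arms.intervention.program_cost", "op": "multiply", "value": 0.5}]},
  {"name": "Intervention costs doubled",
   "edits": [{"path": "arms.intervention.program_cost", "op": "multiply", "value": 2}]},
  {"name": "Hospital costs halved",
   "edits": [{"path": "arms.*.costs.hospitalisation.monthly_cost", "op": "multiply", "value": 0.5},
             {"path": "arms.*.costs.hospitalisation_prac.monthly_cost", "op": "multiply", "value": 0.5}]},
  {"name": "Hospital costs doubled",
   "edits": [{"path": "arms.*.costs.hospitalisation.monthly_cost", "op": "multiply", "value": 2},
             {"path": "arms.*.costs.hospitalisation_prac.monthly_cost", "op": "multiply", "value": 2}]},
  {"name": "P-RAC costs halved",
   "edits": [{"path": "prac_daily_cost", "op": "multiply", "value": 0.5}]},
  {"name": "P-RAC costs doubled",
   "edits": [{"path": "prac_daily_cost", "op": "multiply", "value": 2}]},
  {"name": "Respite RAC costs halved",
   "edits": [{"path": "arms.*.costs.respite_rac.monthly_cost", "op": "multiply", "value": 0.5}]},
  {"name": "Respite RAC costs doubled",
   "edits": [{"path": "arms.*.costs.respite_rac.monthly_cost", "op": "multiply", "value": 2}]},
  {"name": "Prob of receiving HCP doubled",
   "edits": [{"path": "arms.*.costs.home_care_package.monthly_cost", "op": "multiply", "value": 2}]},
  {"name": "Prob of receiving a HCP halved",
   "edits": [{"path": "arms.*.costs.home_care_package.monthly_cost", "op": "multiply", "value": 0.5}]},
  {"name": "Difference in prob of entry to P-RAC between int and SC arms halved",
   "edits": [{"path": "admission_prob_difference", "op": "multiply", "value": 0.5}]},
  {"name": "Difference in prob of entry to P-RAC between int and SC arms doubled",
   "edits": [{"path": "admission_prob_difference", "op": "multiply", "value": 2}]},
  {"name": "Cohort age down by a decade",
   "edits": [{"path": "cohort_start_age", "op": "add", "value": -10}]},
  {"name": "Cohort age up by a decade",
   "edits": [{"path": "cohort_start_age", "op": "add", "value": 10}]},
  {"name": "Dementia-specific excess mortality doubled",
   "edits": [{"path": "mortality.dementia_relative_risk", "op": "multiply", "value": 2}]},
  {"name": "Dementia-specific excess mortality halved",
   "edits": [{"path": "mortality.dementia_relative_risk", "op": "multiply", "value": 0.5}]},
  {"name": "Mortality doubled for people in P-RAC",
   "edits": [{"path": "mortality.state_hazard_multipliers.prac", "op": "multiply", "value": 2}]},
  {"name": "Time horizon decreased to 1 y and difference in prob of entry to P-RAC halved",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 12},
             {"path": "admission_prob_difference", "op": "multiply", "value": 0.5}]},
  {"name": "Time horizon decreased to 3 y and difference in prob of entry to P-RAC halved",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 36},
             {"path": "admission_prob_difference", "op": "multiply", "value": 0.5}]},
  {"name": "Time horizon increased to 7 y and difference in prob of entry to P-RAC doubled",
   "edits": [{"path": "time.horizon_cycles", "op": "set", "value": 84},
             {"path": "admission_prob_difference", "op": "multiply", "value": 2}]}
]
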