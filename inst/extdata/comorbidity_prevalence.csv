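condition,p_white,p_black,p_asian
atrial_fibrillation,0.2983,0.2483,0.2746
heart_failure,0.4350,0.5299,0.4598
hypertension,0.5996,0.7112,0.6151
diabetes,0.2334,0.3358,0.3371
ischemic_stroke,0.1058,0.1697,0.1078
transient_ischemic_attack,0.0654,0.0590,0.0315
systemic_embolism,0.0095,0.0140,0.0087
pulmonary_embolism,0.0438,0.0869,0.0261
prior_myocardial_infarction,0.1283,0.1680,0.1481
stroke_tia_thromboembolism,0.2851,0.3799,0.2709
peripheral_arterial_disease,0.1613,0.1406,0.1428
vascular_disease,0.2556,0.2722,0.2626
coronary_artery_disease,0.3596,0.2826,0.3580
chronic_kidney_disease,0.2495,0.4110,0.3104
liver_disease,0.0666,0.0477,0.0776
chronic_obstructive_pulmonary_disease,0.0645,0.1002,0.0297
prior_smoker,0.0623,0.0846,0.0520
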