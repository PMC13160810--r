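category,group,count
questionnaires,distributed,380
questionnaires,valid,351
role,older_adult,241
role,caregiver,110
gender,women,207
gender,male,144
age,30-60,66
age,60-70,197
age,70plus,88
disease,heart_disease,139
disease,hypertension,101
disease,pneumonia,79
disease,osteoarthritis,32
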