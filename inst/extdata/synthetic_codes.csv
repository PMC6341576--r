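code,category,label
LC01,lung_cancer,
LC02,lung_cancer,
LC03,lung_cancer,
SCC01,scc,
SCC02,scc,
SYMP_COUGH,symptom,cough
SYMP_HAEMOPTYSIS,symptom,haemoptysis
SYMP_CHESTINF,symptom,chest_infection
SYMP_CHESTPAIN,symptom,chest_pain
SYMP_SOB,symptom,shortness_of_breath
SYMP_WTLOSS,symptom,weight_loss
PROC_CXR,procedure,chest_xray
PROC_CT,procedure,cat_scan
PROC_BRONCH,procedure,bronchoscopy
PROC_BIOPSY,procedure,biopsy
SURG_THORAC,surgery,thoracic_surgery
TERM01,terminal_care,
COM_MI,comorbidity,mi
COM_STROKE,comorbidity,ischaemic_stroke
COM_HTN,comorbidity,hypertension
COM_DEPR,comorbidity,depression
COM_ASTHMA,comorbidity,asthma
COM_COPD,comorbidity,copd
SMOK_NON,lifestyle,smoking:non_smoker
SMOK_CURR,lifestyle,smoking:current
SMOK_FORMER,lifestyle,smoking:former
BMI_15_19,lifestyle,bmi:15-19
BMI_20_24,lifestyle,bmi:20-24
BMI_25_29,lifestyle,bmi:25-29
BMI_30PLUS,lifestyle,bmi:>=30
ALC_NONE,lifestyle,alcohol:none
ALC_1_9,lifestyle,alcohol:1-9
ALC_10_20,lifestyle,alcohol:10-20
ALC_21_41,lifestyle,alcohol:21-41
ALC_42PLUS,lifestyle,alcohol:>=42
VISIT,encounter,
NOTE,encounter,
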