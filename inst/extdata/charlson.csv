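category,icd9_prefix,weight,hierarchy_group,severity_rank
myocardial_infarction,410,1,NA,NA
myocardial_infarction,412,1,NA,NA
congestive_heart_failure,428,1,NA,NA
peripheral_vascular_disease,441,1,NA,NA
peripheral_vascular_disease,4439,1,NA,NA
peripheral_vascular_disease,7854,1,NA,NA
peripheral_vascular_disease,V434,1,NA,NA
cerebrovascular_disease,430,1,NA,NA
cerebrovascular_disease,431,1,NA,NA
cerebrovascular_disease,432,1,NA,NA
cerebrovascular_disease,433,1,NA,NA
cerebrovascular_disease,434,1,NA,NA
cerebrovascular_disease,435,1,NA,NA
cerebrovascular_disease,436,1,NA,NA
cerebrovascular_disease,437,1,NA,NA
cerebrovascular_disease,438,1,NA,NA
dementia,290,1,NA,NA
chronic_pulmonary_disease,490,1,NA,NA
chronic_pulmonary_disease,491,1,NA,NA
chronic_pulmonary_disease,492,1,NA,NA
chronic_pulmonary_disease,493,1,NA,NA
chronic_pulmonary_disease,494,1,NA,NA
chronic_pulmonary_disease,495,1,NA,NA
chronic_pulmonary_disease,496,1,NA,NA
chronic_pulmonary_disease,500,1,NA,NA
chronic_pulmonary_disease,501,1,NA,NA
chronic_pulmonary_disease,502,1,NA,NA
chronic_pulmonary_disease,503,1,NA,NA
chronic_pulmonary_disease,504,1,NA,NA
chronic_pulmonary_disease,505,1,NA,NA
chronic_pulmonary_disease,5064,1,NA,NA
rheumatic_disease,7100,1,NA,NA
rheumatic_disease,7101,1,NA,NA
rheumatic_disease,7104,1,NA,NA
rheumatic_disease,7140,1,NA,NA
rheumatic_disease,7141,1,NA,NA
rheumatic_disease,7142,1,NA,NA
rheumatic_disease,71481,1,NA,NA
rheumatic_disease,725,1,NA,NA
peptic_ulcer_disease,531,1,NA,NA
peptic_ulcer_disease,532,1,NA,NA
peptic_ulcer_disease,533,1,NA,NA
peptic_ulcer_disease,534,1,NA,NA
mild_liver_disease,5712,1,liver,1
mild_liver_disease,5714,1,liver,1
mild_liver_disease,5715,1,liver,1
mild_liver_disease,5716,1,liver,1
diabetes,2500,1,diabetes,1
diabetes,2501,1,diabetes,1
diabetes,2502,1,diabetes,1
diabetes,2503,1,diabetes,1
diabetes,2507,1,diabetes,1
diabetes_with_complications,2504,2,diabetes,2
diabetes_with_complications,2505,2,diabetes,2
diabetes_with_complications,2506,2,diabetes,2
hemiplegia_paraplegia,342,2,NA,NA
hemiplegia_paraplegia,3441,2,NA,NA
renal_disease,582,2,NA,NA
renal_disease,5830,2,NA,NA
renal_disease,5831,2,NA,NA
renal_disease,5832,2,NA,NA
renal_disease,5833,2,NA,NA
renal_disease,5834,2,NA,NA
renal_disease,5835,2,NA,NA
renal_disease,5836,2,NA,NA
renal_disease,5837,2,NA,NA
renal_disease,585,2,NA,NA
renal_disease,586,2,NA,NA
renal_disease,588,2,NA,NA
malignancy,140,2,cancer,1
malignancy,141,2,cancer,1
malignancy,142,2,cancer,1
malignancy,143,2,cancer,1
malignancy,144,2,cancer,1
malignancy,145,2,cancer,1
malignancy,146,2,cancer,1
malignancy,147,2,cancer,1
malignancy,148,2,cancer,1
malignancy,149,2,cancer,1
malignancy,150,2,cancer,1
malignancy,151,2,cancer,1
malignancy,152,2,cancer,1
malignancy,153,2,cancer,1
malignancy,154,2,cancer,1
malignancy,155,2,cancer,1
malignancy,156,2,cancer,1
malignancy,157,2,cancer,1
malignancy,158,2,cancer,1
malignancy,159,2,cancer,1
malignancy,160,2,cancer,1
malignancy,161,2,cancer,1
malignancy,162,2,cancer,1
malignancy,163,2,cancer,1
malignancy,164,2,cancer,1
malignancy,165,2,cancer,1
malignancy,166,2,cancer,1
malignancy,167,2,cancer,1
malignancy,168,2,cancer,1
malignancy,169,2,cancer,1
malignancy,170,2,cancer,1
malignancy,171,2,cancer,1
malignancy,172,2,cancer,1
malignancy,174,2,cancer,1
malignancy,175,2,cancer,1
malignancy,176,2,cancer,1
malignancy,177,2,cancer,1
malignancy,178,2,cancer,1
malignancy,179,2,cancer,1
malignancy,180,2,cancer,1
malignancy,181,2,cancer,1
malignancy,182,2,cancer,1
malignancy,183,2,cancer,1
malignancy,184,2,cancer,1
malignancy,185,2,cancer,1
malignancy,186,2,cancer,1
malignancy,187,2,cancer,1
malignancy,188,2,cancer,1
malignancy,189,2,cancer,1
malignancy,190,2,cancer,1
malignancy,191,2,cancer,1
malignancy,192,2,cancer,1
malignancy,193,2,cancer,1
malignancy,194,2,cancer,1
malignancy,195,2,cancer,1
malignancy,200,2,cancer,1
malignancy,201,2,cancer,1
malignancy,202,2,cancer,1
malignancy,203,2,cancer,1
malignancy,204,2,cancer,1
malignancy,205,2,cancer,1
malignancy,206,2,cancer,1
malignancy,207,2,cancer,1
malignancy,208,2,cancer,1
moderate_severe_liver_disease,4560,3,liver,2
moderate_severe_liver_disease,4561,3,liver,2
moderate_severe_liver_disease,4562,3,liver,2
moderate_severe_liver_disease,5722,3,liver,2
moderate_severe_liver_disease,5723,3,liver,2
moderate_severe_liver_disease,5724,3,liver,2
moderate_severe_liver_disease,5728,3,liver,2
metastatic_solid_tumor,196,6,cancer,2
metastatic_solid_tumor,197,6,cancer,2
metastatic_solid_tumor,198,6,cancer,2
metastatic_solid_tumor,199,6,cancer,2
aids_hiv,042,6,NA,NA
aids_hiv,043,6,NA,NA
aids_hiv,044,6,NA,NA
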