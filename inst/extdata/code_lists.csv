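list_name,entry,role,match_rule
RA_diagnosis,714,include,prefix
RA_diagnosis,7143,exclude,prefix
exclusion_inflammatory,696,include,prefix
exclusion_inflammatory,7200,include,prefix
exclusion_inflammatory,555,include,prefix
exclusion_inflammatory,556,include,prefix
exclusion_inflammatory,7143,include,prefix
exclusion_malignancy_hiv,140,include,prefix
exclusion_malignancy_hiv,141,include,prefix
exclusion_malignancy_hiv,142,include,prefix
exclusion_malignancy_hiv,143,include,prefix
exclusion_malignancy_hiv,144,include,prefix
exclusion_malignancy_hiv,145,include,prefix
exclusion_malignancy_hiv,146,include,prefix
exclusion_malignancy_hiv,147,include,prefix
exclusion_malignancy_hiv,148,include,prefix
exclusion_malignancy_hiv,149,include,prefix
exclusion_malignancy_hiv,150,include,prefix
exclusion_malignancy_hiv,151,include,prefix
exclusion_malignancy_hiv,152,include,prefix
exclusion_malignancy_hiv,153,include,prefix
exclusion_malignancy_hiv,154,include,prefix
exclusion_malignancy_hiv,155,include,prefix
exclusion_malignancy_hiv,156,include,prefix
exclusion_malignancy_hiv,157,include,prefix
exclusion_malignancy_hiv,158,include,prefix
exclusion_malignancy_hiv,159,include,prefix
exclusion_malignancy_hiv,160,include,prefix
exclusion_malignancy_hiv,161,include,prefix
exclusion_malignancy_hiv,162,include,prefix
exclusion_malignancy_hiv,163,include,prefix
exclusion_malignancy_hiv,164,include,prefix
exclusion_malignancy_hiv,165,include,prefix
exclusion_malignancy_hiv,166,include,prefix
exclusion_malignancy_hiv,167,include,prefix
exclusion_malignancy_hiv,168,include,prefix
exclusion_malignancy_hiv,169,include,prefix
exclusion_malignancy_hiv,170,include,prefix
exclusion_malignancy_hiv,171,include,prefix
exclusion_malignancy_hiv,172,include,prefix
exclusion_malignancy_hiv,173,include,prefix
exclusion_malignancy_hiv,174,include,prefix
exclusion_malignancy_hiv,175,include,prefix
exclusion_malignancy_hiv,176,include,prefix
exclusion_malignancy_hiv,177,include,prefix
exclusion_malignancy_hiv,178,include,prefix
exclusion_malignancy_hiv,179,include,prefix
exclusion_malignancy_hiv,180,include,prefix
exclusion_malignancy_hiv,181,include,prefix
exclusion_malignancy_hiv,182,include,prefix
exclusion_malignancy_hiv,183,include,prefix
exclusion_malignancy_hiv,184,include,prefix
exclusion_malignancy_hiv,185,include,prefix
exclusion_malignancy_hiv,186,include,prefix
exclusion_malignancy_hiv,187,include,prefix
exclusion_malignancy_hiv,188,include,prefix
exclusion_malignancy_hiv,189,include,prefix
exclusion_malignancy_hiv,190,include,prefix
exclusion_malignancy_hiv,191,include,prefix
exclusion_malignancy_hiv,192,include,prefix
exclusion_malignancy_hiv,193,include,prefix
exclusion_malignancy_hiv,194,include,prefix
exclusion_malignancy_hiv,195,include,prefix
exclusion_malignancy_hiv,196,include,prefix
exclusion_malignancy_hiv,197,include,prefix
exclusion_malignancy_hiv,198,include,prefix
exclusion_malignancy_hiv,199,include,prefix
exclusion_malignancy_hiv,200,include,prefix
exclusion_malignancy_hiv,201,include,prefix
exclusion_malignancy_hiv,202,include,prefix
exclusion_malignancy_hiv,203,include,prefix
exclusion_malignancy_hiv,204,include,prefix
exclusion_malignancy_hiv,205,include,prefix
exclusion_malignancy_hiv,206,include,prefix
exclusion_malignancy_hiv,207,include,prefix
exclusion_malignancy_hiv,208,include,prefix
exclusion_malignancy_hiv,042,include,prefix
exclusion_malignancy_hiv,043,include,prefix
exclusion_malignancy_hiv,044,include,prefix
exclusion_malignancy_hiv,173,exclude,prefix
bdmard_agents,B-ABA,include,exact
bdmard_agents,B-ADA,include,exact
bdmard_agents,B-ETA,include,exact
bdmard_agents,B-GOL,include,exact
bdmard_agents,B-TOC,include,exact
csdmard_agents,MT,include,exact
csdmard_agents,HCQ,include,exact
csdmard_agents,SSZ,include,exact
csdmard_agents,LEF,include,exact
csdmard_agents,AZA,include,exact
csdmard_agents,CSA,include,exact
oral_gc_drugs,PRED,include,exact
oral_gc_drugs,PREDL,include,exact
oral_gc_drugs,MPRED,include,exact
oral_gc_drugs,DEXA,include,exact
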