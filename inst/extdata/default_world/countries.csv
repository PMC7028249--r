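"country_code","name","subregion","region","proportion_sexually_active","sexual_activity_group","group_assignment_source"
"C01","Country C01","Region01.Sub1","Region01",0.0039,"group0_low","dhs_mics_proportion"
"C02","Country C02","Region01.Sub1","Region01",0.0717,"group1_other","dhs_mics_proportion"
"C03","Country C03","Region01.Sub1","Region01",0.0904,"group1_other","dhs_mics_proportion"
"C04","Country C04","Region01.Sub2","Region01",0.1585,"group1_other","dhs_mics_proportion"
"C05","Country C05","Region01.Sub2","Region01",0.4867,"group1_other","dhs_mics_proportion"
"C06","Country C06","Region01.Sub2","Region01",0.0067,"group0_low","dhs_mics_proportion"
"C07","Country C07","Region02.Sub1","Region02",0.0066,"group0_low","dhs_mics_proportion"
"C08","Country C08","Region02.Sub1","Region02",0.215,"group1_other","dhs_mics_proportion"
"C09","Country C09","Region02.Sub1","Region02",0.273,"group1_other","dhs_mics_proportion"
"C10","Country C10","Region02.Sub2","Region02",0.4546,"group1_other","dhs_mics_proportion"
"C11","Country C11","Region02.Sub2","Region02",0.0025,"group0_low","dhs_mics_proportion"
"C12","Country C12","Region02.Sub2","Region02",0.2086,"group1_other","dhs_mics_proportion"
"C13","Country C13","Region03.Sub1","Region03",0.0152,"group0_low","dhs_mics_proportion"
"C14","Country C14","Region03.Sub1","Region03",0.1903,"group1_other","dhs_mics_proportion"
"C15","Country C15","Region03.Sub1","Region03",0.0059,"group0_low","dhs_mics_proportion"
"C16","Country C16","Region03.Sub2","Region03",0.4002,"group1_other","dhs_mics_proportion"
"C17","Country C17","Region03.Sub2","Region03",0.3304,"group1_other","dhs_mics_proportion"
"C18","Country C18","Region03.Sub2","Region03",0.1918,"group1_other","dhs_mics_proportion"
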