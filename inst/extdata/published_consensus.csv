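"disease","setting","scope","slot_id","median_pct","iqr"
"B","prophylaxis","domain","pharmacokinetics",18,4
"B","prophylaxis","domain","bleeding_episodes",32,2
"B","prophylaxis","domain","joint_health",27,3
"B","prophylaxis","domain","adherence_qol",23,6
"A","prophylaxis","domain","pharmacokinetics",19,5.5
"A","prophylaxis","domain","bleeding_episodes",31,4.5
"A","prophylaxis","domain","joint_health",29,4.75
"A","prophylaxis","domain","adherence_qol",21,3.25
"B","on_demand","domain","bleeding_episodes",40,0
"B","on_demand","domain","joint_health",35,2
"B","on_demand","domain","adherence_qol",25,6
"A","on_demand","domain","bleeding_episodes",38,5.5
"A","on_demand","domain","joint_health",37,2.5
"A","on_demand","domain","adherence_qol",25,6
"B","prophylaxis","items:joint_health","pj_count",13,2
"B","prophylaxis","items:joint_health","pj_trend",13,2
"B","prophylaxis","items:joint_health","tj_count",13,5
"B","prophylaxis","items:joint_health","tj_trend",14,1
"B","prophylaxis","items:joint_health","hjhs_change",15,3
"B","prophylaxis","items:joint_health","headus_change",19,3
"B","prophylaxis","items:joint_health","ajbr",13,4
"B","prophylaxis","items:adherence_qol","adherence",32,5
"B","prophylaxis","items:adherence_qol","qol_current",32,1
"B","prophylaxis","items:adherence_qol","qol_change",36,2
"A","prophylaxis","items:joint_health","pj_count",11,5.25
"A","prophylaxis","items:joint_health","pj_trend",15,3
"A","prophylaxis","items:joint_health","tj_count",12,3.25
"A","prophylaxis","items:joint_health","tj_trend",17,4.25
"A","prophylaxis","items:joint_health","hjhs_change",15,3.5
"A","prophylaxis","items:joint_health","headus_change",17,3.5
"A","prophylaxis","items:joint_health","ajbr",13,5
"A","prophylaxis","items:adherence_qol","adherence",33,4
"A","prophylaxis","items:adherence_qol","qol_current",32,3.75
"A","prophylaxis","items:adherence_qol","qol_change",35,1.75
"B","on_demand","items:joint_health","pj_count",18,1
"B","on_demand","items:joint_health","tj_count",19,3
"B","on_demand","items:joint_health","hjhs_change",20,4
"B","on_demand","items:joint_health","headus_change",26,3
"B","on_demand","items:joint_health","ajbr",17,5
"A","on_demand","items:joint_health","pj_count",18,3.25
"A","on_demand","items:joint_health","tj_count",19,2.75
"A","on_demand","items:joint_health","hjhs_change",23,5.25
"A","on_demand","items:joint_health","headus_change",22,4
"A","on_demand","items:joint_health","ajbr",18,7
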