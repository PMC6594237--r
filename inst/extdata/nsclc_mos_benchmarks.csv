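group,sensitivity_label,mos_months,bias_pct
platinum,sim1_63.4,12.3,36.7
platinum,sim2_72.5,11.2,24.4
platinum,ehr_90.6,9.5,5.6
platinum,gold,9.0,NA
other_chemo,sim1_63.4,11.8,53.2
other_chemo,sim2_72.5,10.1,31.2
other_chemo,ehr_90.6,8.2,6.5
other_chemo,gold,7.7,NA
egfr_pos,sim1_63.4,20.7,46.8
egfr_pos,sim2_72.5,19.4,37.6
egfr_pos,ehr_90.6,15.0,6.4
egfr_pos,gold,14.1,NA
egfr_neg,sim1_63.4,21.2,43.2
egfr_neg,sim2_72.5,19.2,29.7
egfr_neg,ehr_90.6,16.0,8.1
egfr_neg,gold,14.8,NA
kras_pos,sim1_63.4,33.4,40.9
kras_pos,sim2_72.5,29.9,25.8
kras_pos,ehr_90.6,24.3,2.5
kras_pos,gold,23.7,NA
kras_neg,sim1_63.4,16.3,39.3
kras_neg,sim2_72.5,14.6,24.8
kras_neg,ehr_90.6,12.4,6.0
kras_neg,gold,11.7,NA
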