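table,output_class,A_odoratum,B_inermis,H_bulbosum,L_perenne,P_alpina
baseline_loo,A_odoratum,184,3,5,13,11
baseline_loo,B_inermis,1,114,10,14,2
baseline_loo,H_bulbosum,4,51,189,5,2
baseline_loo,L_perenne,5,18,0,131,7
baseline_loo,P_alpina,5,14,5,33,178
omit_loo,A_odoratum,181,9,6,16,8
omit_loo,B_inermis,6,91,13,14,6
omit_loo,H_bulbosum,4,52,183,14,0
omit_loo,L_perenne,4,28,1,126,4
omit_loo,P_alpina,4,19,6,26,182
nmf_loo,A_odoratum,185,2,1,15,12
nmf_loo,B_inermis,1,130,9,14,3
nmf_loo,H_bulbosum,2,42,192,8,0
nmf_loo,L_perenne,6,17,1,140,4
nmf_loo,P_alpina,4,8,6,19,181
emsc_loo,A_odoratum,187,3,1,16,10
emsc_loo,B_inermis,1,126,7,14,2
emsc_loo,H_bulbosum,2,44,197,7,0
emsc_loo,L_perenne,5,19,0,136,4
emsc_loo,P_alpina,4,8,4,23,184
popsplit_plsda,A_odoratum,82,4,0,12,1
popsplit_plsda,B_inermis,0,26,6,4,4
popsplit_plsda,H_bulbosum,8,27,94,7,2
popsplit_plsda,L_perenne,4,36,1,46,4
popsplit_plsda,P_alpina,6,7,3,31,87
popsplit_ann,A_odoratum,80,1,0,4,1
popsplit_ann,B_inermis,0,30,20,4,5
popsplit_ann,H_bulbosum,10,22,81,2,1
popsplit_ann,L_perenne,6,39,0,66,2
popsplit_ann,P_alpina,4,8,3,24,89
popsplit_rf,A_odoratum,75,31,2,23,6
popsplit_rf,B_inermis,1,26,10,4,15
popsplit_rf,H_bulbosum,6,4,87,1,3
popsplit_rf,L_perenne,10,34,2,47,2
popsplit_rf,P_alpina,8,5,3,25,72
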