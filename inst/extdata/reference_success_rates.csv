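table,A_odoratum,B_inermis,H_bulbosum,L_perenne,P_alpina,overall
baseline_loo,92,57,90,67,89,79
omit_loo,91,46,88,64,91,76
nmf_loo,93,65,92,71,91,82
emsc_loo,94,63,94,69,92,83
popsplit_plsda,82,26,90,46,89,67
popsplit_ann,80,30,77,66,91,69
popsplit_rf,75,26,84,47,73,61
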