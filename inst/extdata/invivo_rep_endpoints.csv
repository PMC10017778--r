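arm,endpoint,auc_min_ug_mL
SENO,AUC_SEN,15.11
SEN,AUC_SEN,17.24
SENO,AUC_pyrrole_protein_adducts,384.98
SEN,AUC_pyrrole_protein_adducts,628.48
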