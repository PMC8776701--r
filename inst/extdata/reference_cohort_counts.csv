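characteristic,level,n
gender,male,65
gender,female,20
delivery_technique,3D-CRT,50
delivery_technique,VMAT,35
rp_classification,grade_ge2,21
rp_classification,grade_lt2,64
smoking_history,yes,70
smoking_history,no,15
copd,yes,41
copd,no,44
fractionation,60Gy_30fr,56
fractionation,66Gy_33fr,19
fractionation,69Gy_23fr,6
fractionation,72Gy_24fr,4
chemotherapy,yes,39
chemotherapy,no,46
chemo_regimen,cisplatin_vinorelbine,24
chemo_regimen,carboplatin_paclitaxel,10
chemo_regimen,cisplatin_etoposide,2
chemo_regimen,cisplatin_pemetrexed,1
chemo_regimen,others,2
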