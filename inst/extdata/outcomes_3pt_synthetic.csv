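patient_id,grade,age,psa,gleason_group,prescribed_dose_gy
P001,0,71,6.2,1,80
P002,2,68,11.5,3,80
P003,1,77,8.9,2,67.5
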