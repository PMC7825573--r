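patient_id,dose_gy,volume,volume_unit
P001,0,100,percent
P001,20,85,percent
P001,40,55,percent
P001,60,20,percent
P001,80,2,percent
P002,0,1.0,fraction
P002,25,0.8,fraction
P002,50,0.45,fraction
P002,75,0.05,fraction
P003,0,250,cc
P003,30,180,cc
P003,55,90,cc
P003,70,25,cc
P003,82,0,cc
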