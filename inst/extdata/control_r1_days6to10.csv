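tmfc_id,treatment,day,voltage_mV,missing
control_R1,control,6,253.7,0
control_R1,control,6.5,245.1,0
control_R1,control,7,244.4,0
control_R1,control,7.5,259.9,0
control_R1,control,8,259.0,0
control_R1,control,8.5,250.4,0
control_R1,control,9,241.9,0
control_R1,control,9.5,252.6,0
control_R1,control,10,250.2,0
control_R1,control,10.5,253.4,0
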