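side,index,mass_kg,length_cm,width_cm,height_cm
left,1,0.20,12.3,11.7,2.5
left,2,0.18,11.0,10.5,2.5
left,3,0.07,9.0,8.8,2.5
right,1,0.25,12.5,11.9,2.5
right,2,0.18,11.0,10.5,2.5
right,3,0.12,9.2,9.0,2.5
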