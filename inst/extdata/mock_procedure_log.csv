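label,angulation,sid_cm,kv,ma,ms,frames,time_s,dap_gycm2,fov_cm
#1,LAO31/CAU28,101,79,596,5,35,4.7,1.22,15
#2,CAU39,96,79,590,5,27,3.6,0.94,15
#3,RAO6/CRA40,102,99,610,8,34,4.5,1.19,15
#4,LAO35/CRA31,104,101,585,9,42,5.6,1.46,15
#5,LAO42/CAU27,98,87,628,5,32,4.3,1.12,15
#6,LAO34/CAU6,96,83,634,6,31,4.1,1.08,15
#7,RAO2/CRA30,99,80,604,5,39,5.2,1.36,15
#8,RAO33/CRA4,99,77,572,5,32,4.3,1.12,15
#9,RAO33/CRA4,99,71,518,3,131,8.7,4.57,23
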