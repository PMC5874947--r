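lateral_deg,axial_deg,fov_cm,factor_left,factor_right,factor_overall
31,-28,15,0.050,0.085,0.06925
0,-40,15,0.060,0.095,0.07925
-6,40,15,0.030,0.050,0.04100
35,31,15,0.035,0.040,0.03775
42,-27,15,0.045,0.060,0.05325
34,-6,15,0.070,0.090,0.08100
-2,30,15,0.045,0.075,0.06150
-33,4,15,0.080,0.130,0.10750
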