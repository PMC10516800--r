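roi_id,structure,subdivision,domain_label,bregma_mm
CPr+1.3_a,CP,CPr,CPr.a,1.3
CPr+1.3_b,CP,CPr,CPr.b,1.3
CPr+1.3_c,CP,CPr,CPr.c,1.3
CPr+1.3_d,CP,CPr,CPr.d,1.3
CPr+1.3_e,CP,CPr,CPr.e,1.3
CPr+0.9_a,CP,CPr,CPr.a,0.9
CPr+0.9_b,CP,CPr,CPr.b,0.9
CPr+0.9_c,CP,CPr,CPr.c,0.9
CPr+0.9_d,CP,CPr,CPr.d,0.9
CPr+0.9_e,CP,CPr,CPr.e,0.9
CPr+0.9_f,CP,CPr,CPr.f,0.9
CPr+0.9_g,CP,CPr,CPr.g,0.9
CPr+0.9_h,CP,CPr,CPr.h,0.9
CPi+0.5_a,CP,CPi,CPi.a,0.5
CPi+0.5_b,CP,CPi,CPi.b,0.5
CPi+0.5_c,CP,CPi,CPi.c,0.5
CPi+0.5_d,CP,CPi,CPi.d,0.5
CPi+0.5_e,CP,CPi,CPi.e,0.5
CPi+0.5_f,CP,CPi,CPi.f,0.5
CPi+0.5_g,CP,CPi,CPi.g,0.5
CPi+0.5_h,CP,CPi,CPi.h,0.5
CPi+0.5_i,CP,CPi,CPi.i,0.5
CPi+0.1_a,CP,CPi,CPi.a,0.1
CPi+0.1_b,CP,CPi,CPi.b,0.1
CPi+0.1_c,CP,CPi,CPi.c,0.1
CPi+0.1_d,CP,CPi,CPi.d,0.1
CPi+0.1_e,CP,CPi,CPi.e,0.1
CPi+0.1_f,CP,CPi,CPi.f,0.1
CPi+0.1_g,CP,CPi,CPi.g,0.1
CPi+0.1_h,CP,CPi,CPi.h,0.1
CPi+0.1_i,CP,CPi,CPi.i,0.1
CPi+0.1_j,CP,CPi,CPi.j,0.1
CPi+0.1_k,CP,CPi,CPi.k,0.1
CPi-0.2_a,CP,CPi,CPi.a,-0.2
CPi-0.2_b,CP,CPi,CPi.b,-0.2
CPi-0.2_c,CP,CPi,CPi.c,-0.2
CPi-0.2_d,CP,CPi,CPi.d,-0.2
CPi-0.2_e,CP,CPi,CPi.e,-0.2
CPi-0.2_f,CP,CPi,CPi.f,-0.2
CPi-0.2_g,CP,CPi,CPi.g,-0.2
CPi-0.2_h,CP,CPi,CPi.h,-0.2
CPi-0.2_i,CP,CPi,CPi.i,-0.2
CPi-0.2_j,CP,CPi,CPi.j,-0.2
CPi-0.2_k,CP,CPi,CPi.k,-0.2
CPi-0.5_a,CP,CPi,CPi.a,-0.5
CPi-0.5_b,CP,CPi,CPi.b,-0.5
CPi-0.5_c,CP,CPi,CPi.c,-0.5
CPi-0.5_d,CP,CPi,CPi.d,-0.5
CPi-0.5_e,CP,CPi,CPi.e,-0.5
CPi-0.5_f,CP,CPi,CPi.f,-0.5
CPi-0.5_g,CP,CPi,CPi.g,-0.5
CPi-0.5_h,CP,CPi,CPi.h,-0.5
CPc-0.8_a,CP,CPc,CPc.a,-0.8
CPc-0.8_b,CP,CPc,CPc.b,-0.8
CPc-0.8_c,CP,CPc,CPc.c,-0.8
CPc-0.8_d,CP,CPc,CPc.d,-0.8
CPc-0.8_e,CP,CPc,CPc.e,-0.8
CPc-0.8_f,CP,CPc,CPc.f,-0.8
CPc-1.2_a,CP,CPc,CPc.a,-1.2
CPc-1.2_b,CP,CPc,CPc.b,-1.2
CPc-1.2_c,CP,CPc,CPc.c,-1.2
CPc-1.2_d,CP,CPc,CPc.d,-1.2
CPc-1.2_e,CP,CPc,CPc.e,-1.2
CPc-1.6_a,CP,CPc,CPc.a,-1.6
CPc-1.6_b,CP,CPc,CPc.b,-1.6
CPc-1.6_c,CP,CPc,CPc.c,-1.6
SNr-2.9_a,SNr,SNr,SNr.a,-2.9
SNr-2.9_b,SNr,SNr,SNr.b,-2.9
SNr-2.9_c,SNr,SNr,SNr.c,-2.9
SNr-2.9_d,SNr,SNr,SNr.d,-2.9
SNr-2.9_e,SNr,SNr,SNr.e,-2.9
SNr-3.2_a,SNr,SNr,SNr.a,-3.2
SNr-3.2_b,SNr,SNr,SNr.b,-3.2
SNr-3.2_c,SNr,SNr,SNr.c,-3.2
SNr-3.2_d,SNr,SNr,SNr.d,-3.2
SNr-3.2_e,SNr,SNr,SNr.e,-3.2
SNr-3.2_f,SNr,SNr,SNr.f,-3.2
SNr-3.2_g,SNr,SNr,SNr.g,-3.2
SNr-3.4_a,SNr,SNr,SNr.a,-3.4
SNr-3.4_b,SNr,SNr,SNr.b,-3.4
SNr-3.4_c,SNr,SNr,SNr.c,-3.4
SNr-3.4_d,SNr,SNr,SNr.d,-3.4
SNr-3.4_e,SNr,SNr,SNr.e,-3.4
SNr-3.4_f,SNr,SNr,SNr.f,-3.4
SNr-3.4_g,SNr,SNr,SNr.g,-3.4
SNr-3.7_a,SNr,SNr,SNr.a,-3.7
SNr-3.7_b,SNr,SNr,SNr.b,-3.7
SNr-3.7_c,SNr,SNr,SNr.c,-3.7
SNr-3.7_d,SNr,SNr,SNr.d,-3.7
SNr-3.7_e,SNr,SNr,SNr.e,-3.7
SNr-3.7_f,SNr,SNr,SNr.f,-3.7
GPe-0.5_a,GPe,GPe,GPe.a,-0.5
GPe-0.5_b,GPe,GPe,GPe.b,-0.5
GPe-0.5_c,GPe,GPe,GPe.c,-0.5
GPe-0.5_d,GPe,GPe,GPe.d,-0.5
GPe-0.5_e,GPe,GPe,GPe.e,-0.5
GPe-0.5_f,GPe,GPe,GPe.f,-0.5
GPe-0.8_a,GPe,GPe,GPe.a,-0.8
GPe-0.8_b,GPe,GPe,GPe.b,-0.8
GPe-0.8_c,GPe,GPe,GPe.c,-0.8
GPe-0.8_d,GPe,GPe,GPe.d,-0.8
GPe-0.8_e,GPe,GPe,GPe.e,-0.8
GPe-0.8_f,GPe,GPe,GPe.f,-0.8
GPe-0.8_g,GPe,GPe,GPe.g,-0.8
GPe-0.8_h,GPe,GPe,GPe.h,-0.8
GPe-1.2_a,GPe,GPe,GPe.a,-1.2
GPe-1.2_b,GPe,GPe,GPe.b,-1.2
GPe-1.2_c,GPe,GPe,GPe.c,-1.2
GPe-1.2_d,GPe,GPe,GPe.d,-1.2
GPe-1.2_e,GPe,GPe,GPe.e,-1.2
GPe-1.2_f,GPe,GPe,GPe.f,-1.2
GPe-1.2_g,GPe,GPe,GPe.g,-1.2
GPe-1.6_a,GPe,GPe,GPe.a,-1.6
GPe-1.6_b,GPe,GPe,GPe.b,-1.6
GPe-1.6_c,GPe,GPe,GPe.c,-1.6
GPe-1.6_d,GPe,GPe,GPe.d,-1.6
GPe-1.6_e,GPe,GPe,GPe.e,-1.6
GPe-1.6_f,GPe,GPe,GPe.f,-1.6
M1+1.3_a,MOTOR,M1,M1.a,1.3
M1+1.3_b,MOTOR,M1,M1.b,1.3
M2+1.3_a,MOTOR,M2,M2.a,1.3
M2+1.3_b,MOTOR,M2,M2.b,1.3
M1+0.8_a,MOTOR,M1,M1.a,0.8
M1+0.8_b,MOTOR,M1,M1.b,0.8
M2+0.8_a,MOTOR,M2,M2.a,0.8
M2+0.8_b,MOTOR,M2,M2.b,0.8
M1+0.1_a,MOTOR,M1,M1.a,0.1
M1+0.1_b,MOTOR,M1,M1.b,0.1
M2+0.1_a,MOTOR,M2,M2.a,0.1
M2+0.1_b,MOTOR,M2,M2.b,0.1
M1-0.8_a,MOTOR,M1,M1.a,-0.8
M1-0.8_b,MOTOR,M1,M1.b,-0.8
M1-0.8_c,MOTOR,M1,M1.c,-0.8
M1-1.6_a,MOTOR,M1,M1.a,-1.6
M1-1.6_b,MOTOR,M1,M1.b,-1.6
M1-1.6_c,MOTOR,M1,M1.c,-1.6
Cg1+1.8_a,PFC,Cg1,Cg1.a,1.8
Cg2+1.8_a,PFC,Cg2,Cg2.a,1.8
IL+1.8_a,PFC,IL,IL.a,1.8
PrL+1.8_a,PFC,PrL,PrL.a,1.8
PrL+1.8_b,PFC,PrL,PrL.b,1.8
Cg1+1.3_a,PFC,Cg1,Cg1.a,1.3
Cg2+1.3_a,PFC,Cg2,Cg2.a,1.3
Cg2+1.3_b,PFC,Cg2,Cg2.b,1.3
IL+1.3_a,PFC,IL,IL.a,1.3
PrL+1.3_a,PFC,PrL,PrL.a,1.3
Cg1+0.8_a,PFC,Cg1,Cg1.a,0.8
Cg1+0.8_b,PFC,Cg1,Cg1.b,0.8
Cg2+0.8_a,PFC,Cg2,Cg2.a,0.8
Cg2+0.8_b,PFC,Cg2,Cg2.b,0.8
PrL+0.8_a,PFC,PrL,PrL.a,0.8
Cg1+0.1_a,PFC,Cg1,Cg1.a,0.1
Cg1+0.1_b,PFC,Cg1,Cg1.b,0.1
Cg2+0.1_a,PFC,Cg2,Cg2.a,0.1
Cg2+0.1_b,PFC,Cg2,Cg2.b,0.1
AD-0.5_a,TH,AD,AD.a,-0.5
AM-0.5_a,TH,AM,AM.a,-0.5
AM-0.5_b,TH,AM,AM.b,-0.5
AV-0.5_a,TH,AV,AV.a,-0.5
AV-0.5_b,TH,AV,AV.b,-0.5
CM-0.8_a,TH,CM,CM.a,-0.8
MD-0.8_a,TH,MD,MD.a,-0.8
MD-0.8_b,TH,MD,MD.b,-0.8
VA/VL-0.8_a,TH,VA/VL,VA/VL.a,-0.8
VA/VL-0.8_b,TH,VA/VL,VA/VL.b,-0.8
VA/VL-0.8_c,TH,VA/VL,VA/VL.c,-0.8
CM-1.2_a,TH,CM,CM.a,-1.2
MD-1.2_a,TH,MD,MD.a,-1.2
MD-1.2_b,TH,MD,MD.b,-1.2
VA/VL-1.2_a,TH,VA/VL,VA/VL.a,-1.2
VA/VL-1.2_b,TH,VA/VL,VA/VL.b,-1.2
VM-1.2_a,TH,VM,VM.a,-1.2
MD-1.6_a,TH,MD,MD.a,-1.6
MD-1.6_b,TH,MD,MD.b,-1.6
VM-1.6_a,TH,VM,VM.a,-1.6
VM-1.6_b,TH,VM,VM.b,-1.6
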