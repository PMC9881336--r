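participant_id,dataset,group,sex,paretic_side,age,device,le_fugl_meyer,speed_1,speed_2,speed_3,speed_4
P01,1,stroke,M,left,66,AFO,18,0.80,0.90,1.10,1.30
P02,1,stroke,M,left,50,None,19,0.90,1.00,1.10,1.20
P03,1,stroke,M,left,74,AFO,17,0.30,0.40,0.50,0.70
P04,1,stroke,F,left,59,None,31,0.70,0.80,0.90,1.00
P05,1,stroke,M,right,61,AFO,14,1.00,1.10,1.20,1.30
P06,1,stroke,F,left,66,None,21,0.40,0.50,0.50,0.60
P07,1,stroke,F,left,78,None,24,0.70,0.80,0.90,1.00
P08,1,stroke,M,right,57,None,15,0.60,0.80,0.90,1.10
P09,1,stroke,M,right,75,None,31,0.70,0.90,1.10,1.30
P10,1,stroke,F,left,51,AFO,20,0.40,0.50,0.60,0.70
P11,1,stroke,M,right,47,None,25,0.80,0.90,1.00,1.10
P12,1,stroke,M,right,60,None,25,0.90,1.00,1.20,1.30
P13,1,stroke,M,left,52,AFO,20,0.80,1.00,1.20,1.40
P14,1,stroke,F,right,62,SPC,25,0.50,0.60,0.80,1.00
P15,1,stroke,M,right,72,None,32,0.80,0.90,1.00,1.20
P16,1,stroke,M,right,71,"AFO, SPC",19,0.70,0.80,0.90,
P17,1,stroke,M,right,77,None,22,0.70,0.80,0.90,1.10
P18,1,stroke,F,left,45,None,23,0.90,1.00,1.10,
P19,1,stroke,M,right,73,None,31,0.70,0.80,1.00,1.30
P20,1,stroke,M,left,78,SPC,23,0.50,0.60,0.70,0.90
P21,2,stroke,M,left,42,Not reported,22,0.77,0.96,1.15,1.24
P22,2,stroke,F,right,56,Not reported,33,0.46,0.57,0.68,0.81
P23,2,stroke,F,right,68,Not reported,23,0.21,0.26,0.31,0.56
P24,2,stroke,M,right,57,Not reported,17,0.48,0.61,0.72,1.00
P25,2,stroke,M,left,52,Not reported,32,0.82,1.02,1.22,1.35
P26,2,stroke,M,left,67,Not reported,27,0.26,0.33,0.40,
P27,2,stroke,M,left,54,Not reported,31,0.28,0.35,0.42,0.60
P28,2,stroke,M,right,60,Not reported,33,0.22,0.28,0.34,0.57
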