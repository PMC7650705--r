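trait,n,mean,sd,minimum,maximum,definition
BW6,350,84.18,10.31,58,117,Body weight at 6 months (kg)
WH6,354,94.37,5.26,82,108,Withers height at 6 months (cm)
BL6,354,91.89,7.379,73,116,Body length at 6 months (cm)
CG6,354,124.03,7.809,100,144,Chest girth at 6 months (cm)
BW12,343,82.57,10.51,48,113,Body weight at 12 months (kg)
WH12,349,90.49,4.18,81,102,Withers height at 12 months (cm)
BL12,349,95.93,4.957,80,113,Body length at 12 months (cm)
CG12,349,117.16,5.08,102,134,Chest girth at 12 months (cm)
BW30,263,155.42,15.23,108,203,Body weight at 30 months (kg)
WH30,267,99.55,4.997,90,117,Withers height at 30 months (cm)
BL30,265,113.17,5.696,96,126,Body length at 30 months (cm)
CG30,261,146.97,8.266,122,173,Chest girth at 30 months (cm)
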