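patient,sensitivity,specificity,ppv,npv,auc,mcc,tumor_free
1,0.91,0.55,0.79,0.77,0.76,0.51,FALSE
2,NA,0.00,0,NA,NA,NA,TRUE
3,NA,0.55,0,1.00,NA,NA,TRUE
4,NA,0.99,0,1.00,NA,NA,TRUE
6,0.55,0.87,0.42,0.92,0.79,0.38,FALSE
7,0.66,0.79,0.64,0.81,0.78,0.45,FALSE
8,NA,1.00,0,1.00,NA,NA,TRUE
9,0.95,0.67,0.05,1.00,0.84,0.18,FALSE
10,0.85,0.88,0.30,0.99,0.89,0.46,FALSE
11,0.91,0.72,0.98,0.40,0.89,0.49,FALSE
Mean,0.81,0.70,0.53,0.82,0.83,0.41,NA
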