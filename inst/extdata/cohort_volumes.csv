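aneurysm_id,patient_id,age,sex,location,size_bl_mm,size_bl_sd,vol_bl_mm3,vol_bl_sd,size_fu_mm,size_fu_sd,vol_fu_mm3,vol_fu_sd,fu_interval_y,elapss_3y_risk
A1,1,70,F,MCA,6.64,0.12,65.05,2.41,6.85,0.09,81.59,1.40,6,17.5
A2,2,79,M,AComA,7.49,0.14,87.79,1.96,6.92,0.04,91.72,0.76,3,17.5
A3,3,58,F,MCA,4.60,0.07,22.04,0.44,5.19,0.10,27.53,0.72,4,42.7
A4,4,68,M,MCA,3.49,0.17,12.41,1.21,3.87,0.12,14.26,0.85,5,11.7
A5,4,68,M,PComA,6.71,0.16,58.13,2.02,6.33,0.08,57.56,1.80,5,11.7
A6,5,52,M,MCA,4.09,0.10,17.89,0.77,4.42,0.06,23.42,0.49,4,17.5
A7,6,32,M,VA,9.80,0.11,203.73,3.87,10.38,0.14,220.85,3.20,5,7.8
A8,7,66,F,ICA bifur,4.91,0.09,31.08,0.59,4.64,0.13,31.01,1.27,5,25.8
A9,8,69,F,MCA,5.06,0.04,36.36,1.01,5.06,0.09,36.89,1.41,4,17.5
A10,9,51,F,BA,7.84,0.20,62.20,2.32,8.95,0.07,164.27,4.20,2,17.5
A11,10,71,M,ICA bifur,7.99,0.10,102.07,0.98,8.04,0.12,90.82,0.93,4,11.7
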