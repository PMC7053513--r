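parameter,unit,nacl_M,value,sd
mu,1/h,0,1.19,0.02
mu,1/h,0.3,0.88,0.01
mu,1/h,0.6,0.69,0.01
mu,1/h,0.9,0.57,0.01
mu,1/h,1.2,0.39,0.00
mu,1/h,1.8,0.24,0.00
Y_XS,gCDW/mol,0,83.1,1.1
Y_XS,gCDW/mol,0.3,77.2,0.9
Y_XS,gCDW/mol,0.6,74.6,1.1
Y_XS,gCDW/mol,0.9,70.7,1.3
Y_XS,gCDW/mol,1.2,67.3,0.9
Y_XS,gCDW/mol,1.8,58.7,0.7
q_s,mmol/gCDW/h,0,14.4,0.3
q_s,mmol/gCDW/h,0.3,11.5,0.2
q_s,mmol/gCDW/h,0.6,9.3,0.2
q_s,mmol/gCDW/h,0.9,8.0,0.2
q_s,mmol/gCDW/h,1.2,5.8,0.1
q_s,mmol/gCDW/h,1.8,4.0,0.1
Y_Acetate,mmol/mol,0,669,21
Y_Acetate,mmol/mol,0.3,526,24
Y_Acetate,mmol/mol,0.6,490,19
Y_Acetate,mmol/mol,0.9,422,41
Y_Acetate,mmol/mol,1.2,346,26
Y_Acetate,mmol/mol,1.8,253,22
Y_Pyruvate,mmol/mol,0,6.4,0.3
Y_Pyruvate,mmol/mol,0.3,7.6,0.4
Y_Pyruvate,mmol/mol,0.6,2.9,0.1
Y_Pyruvate,mmol/mol,0.9,1.7,0.1
Y_Pyruvate,mmol/mol,1.2,2.2,0.2
Y_Pyruvate,mmol/mol,1.8,20.1,1.6
Y_Lactate,mmol/mol,0,4.4,0.3
Y_Lactate,mmol/mol,0.3,3.6,0.2
Y_Lactate,mmol/mol,0.6,8.3,0.4
Y_Lactate,mmol/mol,0.9,15.0,0.6
Y_Lactate,mmol/mol,1.2,20.3,0.6
Y_Lactate,mmol/mol,1.8,37.7,2.0
Y_Succinate,mmol/mol,0,62.6,3.2
Y_Succinate,mmol/mol,0.3,22.7,1.0
Y_Succinate,mmol/mol,0.6,14.7,0.7
Y_Succinate,mmol/mol,0.9,13.4,0.6
Y_Succinate,mmol/mol,1.2,10.0,0.4
Y_Succinate,mmol/mol,1.8,5.8,0.6
Y_Oxoglutarate,mmol/mol,0,9.7,0.4
Y_Oxoglutarate,mmol/mol,0.3,2.3,0.1
Y_Oxoglutarate,mmol/mol,0.6,1.3,0.1
Y_Oxoglutarate,mmol/mol,0.9,0.7,0.1
Y_Oxoglutarate,mmol/mol,1.2,1.2,0.1
Y_Oxoglutarate,mmol/mol,1.8,1.6,0.1
AEC,dimensionless,0,0.8336,NA
AEC,dimensionless,0.6,0.7659,NA
AEC,dimensionless,1.2,0.8612,NA
NADH_NAD,dimensionless,0,0.0079,NA
NADH_NAD,dimensionless,0.6,0.0260,NA
NADH_NAD,dimensionless,1.2,0.0191,NA
NADPH_NADP,dimensionless,0,0.5162,NA
NADPH_NADP,dimensionless,0.6,0.4330,NA
NADPH_NADP,dimensionless,1.2,1.0551,NA
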