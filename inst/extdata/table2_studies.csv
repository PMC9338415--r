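study,role,subscale,pre_mean,pre_sd,post_mean,post_sd,change_mean,change_sd,n,t_printed,d_printed
DST,dst,NA,1.57,0.56,1.84,0.70,0.27,0.61,103,-4.51,0.427
DST,dst,PA,3.08,0.65,3.37,0.85,0.29,0.61,103,-4.84,0.382
TSST_A,tsst,NA,1.28,0.38,1.82,0.66,0.55,0.68,26,-4.08,1.015
TSST_A,tsst,PA,2.95,0.45,2.94,0.59,-0.01,0.51,26,0.11,0.022
TSST_B,tsst,NA,1.33,0.32,1.66,0.57,0.32,0.44,26,-3.75,0.694
TSST_B,tsst,PA,2.95,0.56,2.97,0.64,0.02,0.45,26,-0.17,0.026
TSST_C,tsst,NA,1.36,0.33,1.51,0.71,0.16,0.68,20,-1.02,0.281
TSST_C,tsst,PA,2.75,0.42,3.02,0.96,0.27,0.82,20,-1.47,0.363
TSST_D,tsst,NA,1.43,0.56,1.85,0.72,0.42,0.53,50,-5.64,0.655
TSST_D,tsst,PA,3.02,0.57,2.88,0.68,-0.14,0.47,50,2.10,0.221
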