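metric,yield_rsm,yield_ann,tpc_rsm,tpc_ann,tfc_rsm,tfc_ann,antioxidant_rsm,antioxidant_ann
rmse,0.1630,0.1259,0.0353,0.0224,0.1442,0.0604,0.5298,0.2558
nmse,0.0052,0.0040,0.0036,0.0023,0.0228,0.0095,0.0094,0.0045
mse,0.0266,0.0158,0.0012,0.0005,0.0208,0.0036,0.2807,0.0655
nrmse,0.0008,0.0005,0.0001,0.0001,0.0033,0.0006,0.0050,0.0012
mpe,0.4500,0.2099,0.3160,0.1218,2.0121,0.4388,0.7860,0.1799
aad,0.1416,0.0670,0.0306,0.0120,0.1248,0.0295,0.4376,0.1040
r2,0.9633,0.9781,0.9622,0.9848,0.9317,0.9883,0.9171,0.9807
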