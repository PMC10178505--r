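run_id,space_type,amplitude,time,ethanol,applied_energy,calorimetric_energy,yield,yield_rsm,yield_ann,tpc,tpc_rsm,tpc_ann,tfc,tfc_rsm,tfc_ann,antioxidant,antioxidant_rsm,antioxidant_ann
1,center,45,10,50,16744,294.34,31.65,31.91,31.90,9.81,9.85,9.85,6.80,6.71,6.69,57.04,57.84,57.85
2,center,45,10,50,16744,277.73,32.14,31.91,31.90,9.89,9.85,9.85,6.78,6.71,6.69,57.74,57.84,57.85
3,factorial,60,5,40,11187,302.98,30.65,30.51,30.65,9.49,9.48,9.49,6.32,6.09,6.32,55.23,54.70,55.23
4,center,45,10,50,16744,837.19,31.74,31.91,31.90,9.82,9.85,9.85,6.85,6.71,6.69,57.87,57.84,57.85
5,factorial,30,15,60,18366,97.68,31.16,31.29,31.16,9.63,9.60,9.63,5.97,6.14,5.97,56.55,56.71,56.55
6,factorial,30,5,60,6261,188.38,31.26,31.11,31.26,9.57,9.56,9.57,5.72,5.70,5.72,56.93,56.35,56.93
7,factorial,30,5,40,7390,173.16,28.71,28.84,28.71,9.38,9.31,9.38,5.39,5.21,5.39,53.21,52.34,53.21
8,axial,45,2,50,2846,166.50,30.45,30.42,30.45,9.47,9.53,9.47,5.49,5.78,5.49,53.86,54.89,53.86
9,axial,70,10,50,23389,336.38,31.73,31.68,31.73,9.82,9.82,9.82,6.88,7.01,6.88,57.80,57.55,57.80
10,axial,20,10,50,10390,134.66,30.11,30.17,30.11,9.38,9.42,9.38,5.53,5.49,5.53,53.39,54.16,53.39
11,factorial,30,15,40,22332,219.78,31.31,31.10,31.31,9.62,9.63,9.62,5.68,5.72,5.68,54.39,54.07,54.39
12,axial,45,10,67,13877,158.85,31.62,31.59,31.62,9.75,9.76,9.75,6.69,6.57,6.69,58.58,58.38,58.58
13,axial,45,18,50,33414,116.80,32.12,32.16,32.12,9.89,9.88,9.89,6.71,6.51,6.71,57.62,57.12,57.62
14,center,45,10,50,16744,170.09,32.21,31.91,31.90,9.90,9.85,9.85,6.67,6.71,6.69,58.59,57.84,57.85
15,center,45,10,50,16744,173.16,32.05,31.91,31.90,9.88,9.85,9.85,6.54,6.71,6.69,57.73,57.84,57.85
16,factorial,60,15,40,30957,109.41,32.24,32.39,32.24,9.88,9.86,9.88,6.57,6.52,6.57,56.79,56.99,56.79
17,axial,45,10,33,17820,166.50,30.46,30.50,30.46,9.48,9.52,9.48,5.48,5.70,5.48,53.12,53.84,53.12
18,factorial,60,5,60,10050,173.16,31.42,31.62,31.42,9.84,9.80,9.84,6.82,6.71,6.82,57.52,57.47,57.52
19,factorial,60,15,60,28857,146.52,31.57,31.43,31.57,9.88,9.91,9.88,6.96,7.07,6.96,57.89,58.39,57.89
20,center,45,10,50,16744,173.16,31.67,31.91,31.90,9.80,9.85,9.85,6.63,6.71,6.69,58.13,57.84,57.85
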