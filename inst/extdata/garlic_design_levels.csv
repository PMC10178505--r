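factor,units,minus_alpha,minus_one,center,plus_one,plus_alpha
amplitude,%,19.77,30,45,60,70.23
time,min,1.60,5,10,15,18.40
ethanol,%,33.18,40,50,60,66.82
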