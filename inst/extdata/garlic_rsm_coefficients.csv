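term,yield,tpc,tfc,antioxidant
b0,31.91,9.85,6.71,57.84
b1,0.4514,0.1194,0.4526,1.01
b2,0.5161,0.1052,0.2183,0.6629
b3,0.3259,0.0735,0.2596,1.35
b12,-0.0950,0.0163,-0.0188,0.1412
b13,-0.2875,0.0187,0.0337,-0.3113
b23,-0.5175,-0.0662,-0.0188,-0.3438
b11,-0.3482,-0.0794,-0.1614,-0.6993
b22,-0.2192,-0.0511,-0.1985,-0.6481
b33,-0.3058,-0.0740,-0.2038,-0.6092
r2,0.963,0.962,0.932,0.917
adj_r2,0.930,0.928,0.870,0.842
lack_of_fit_p,0.660,0.336,0.051,0.109
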