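# Illustrative synthetic water-like equation of state (closed-form,
# generated by water_like_eos(); NOT measured data). Columns:
# temperature (K), number density (A^-3), isothermal compressibility
# (bar^-1), thermal expansion coefficient (K^-1).
T_K,rho_A3,kappaT_bar,alpha_K
260,0.0335866,4.88695e-05,2.2025e-05
280,0.0335282,4.63561e-05,0.000152025
300,0.0333829,4.49077e-05,0.000282025
320,0.0331521,4.44306e-05,0.000412025
340,0.0328373,4.48941e-05,0.000542025
360,0.032441,4.63279e-05,0.000672025
380,0.0319663,4.8825e-05,0.000802025
400,0.0314168,5.25519e-05,0.000932025
420,0.0307965,5.77671e-05,0.00106203
440,0.0301101,6.48513e-05,0.00119203
460,0.0293626,7.43538e-05,0.00132202
480,0.0285592,8.70631e-05,0.00145203
500,0.0277058,0.000104114,0.00158202
520,0.026808,0.000127155,0.00171202
540,0.0258719,0.0001586,0.00184203
560,0.0249038,0.000202032,0.00197202
580,0.0239096,0.000262834,0.00210202
600,0.0228954,0.000349213,0.00223202
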