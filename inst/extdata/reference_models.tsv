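# Coefficient listings (standardized feature scale) of two previously
# reported 3-channel accuracy models for this task, used as worked examples
# and as fixtures for model-application checks. Features are labeled by the
# nominal frequency convention of the original listing ("8Hz_Fz" ~ the
# 6-9 Hz band at Fz); empty cells are zero (unselected) coefficients.
feature	model_a	model_b
Intercept	0.5437	-0.8258
8Hz_Fz		0.0347
8Hz_Cz
8Hz_Pz
12Hz_Fz
12Hz_Cz	0.0101
12Hz_Pz		0.0124
16Hz_Fz		0.0240
16Hz_Cz
16Hz_Pz
20Hz_Fz
20Hz_Cz
20Hz_Pz
24Hz_Fz
24Hz_Cz	0.0278
24Hz_Pz
28Hz_Fz	0.0060
28Hz_Cz		0.0475
28Hz_Pz
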