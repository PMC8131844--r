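refractive_index	density_g_per_ml
1.3860	1.53157
1.3900	1.57278
1.3950	1.62429
1.4000	1.67580
1.4040	1.71701
1.4100	1.77882
1.4150	1.83033
1.4200	1.88184
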