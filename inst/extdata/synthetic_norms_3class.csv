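sex,age_low,age_high,poor_below_ml_kg_min,good_at_or_above_ml_kg_min
1,18,30,38,45
1,30,40,35,42
1,40,50,32,39
1,50,70,28,36
0,18,30,30,38
0,30,40,28,35
0,40,50,26,32
0,50,70,24,30
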