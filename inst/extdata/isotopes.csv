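element,base_mass,a0,a1,a2,a3,a4
C,12,0.9893,0.0107,,,
H,1,0.999885,0.000115,,,
N,14,0.99636,0.00364,,,
O,16,0.99757,0.00038,0.00205,,
Si,28,0.92223,0.04685,0.03092,,
S,32,0.9499,0.0075,0.0425,0,0.0001
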