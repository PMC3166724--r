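state,S1,S2,S3,S4,S5,S6,S7
S1,0.95,0.20,0.00,0.00,0.00,0.01,0.04
S2,0.00,0.90,0.00,0.04,0.00,0.01,0.05
S3,0.00,0.00,0.62,0.25,0.01,0.02,0.10
S4,0.00,0.01,0.03,0.80,0.02,0.07,0.07
S5,0.00,0.01,0.01,0.35,0.40,0.01,0.22
S6,0.02,0.00,0.00,0.04,0.00,0.85,0.09
S7,0.01,0.03,0.01,0.18,0.03,0.12,0.62
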