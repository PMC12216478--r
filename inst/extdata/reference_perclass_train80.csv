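"class","accuracy","precision","recall","fmeasure","mcc"
1,99.61,98.72,92.77,95.65,95.5
2,99.44,98.29,98.29,98.29,97.96
3,99.39,96.05,90.12,92.99,92.72
4,99.22,97.15,98.84,97.99,97.51
5,99.44,97.24,99.3,98.26,97.93
6,99.44,97.89,99.46,98.67,98.32
7,99.5,93.44,91.94,92.68,92.43
8,99.78,98.67,98.67,98.67,98.54
9,99.5,99.12,93.33,96.14,95.92
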