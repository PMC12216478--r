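"class","accuracy","precision","recall","fmeasure","mcc"
1,99.11,91.89,89.47,90.67,90.21
2,98.66,95.04,97.45,96.23,95.43
3,99.36,100,85.07,91.94,91.93
4,99.04,96.77,98.36,97.56,96.97
5,98.92,95.97,97.14,96.55,95.91
6,99.36,97.26,99.69,98.46,98.07
7,99.11,92.68,77.55,84.44,84.34
8,99.43,97.71,95.52,96.6,96.3
9,99.36,94.74,94.74,94.74,94.4
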