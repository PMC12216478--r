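"class","accuracy","precision","recall","fmeasure","mcc"
1,99.4,97.22,92.11,94.59,94.32
2,99.4,98.02,98.02,98.02,97.67
3,99.11,100,78.57,88,88.23
4,98.51,94.89,97.74,96.3,95.38
5,98.96,95.65,98.21,96.92,96.3
6,99.26,96.58,100,98.26,97.81
7,99.26,96,85.71,90.57,90.34
8,99.7,95.92,100,97.92,97.78
9,98.96,95.12,88.64,91.76,91.27
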