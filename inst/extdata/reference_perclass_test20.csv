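"class","accuracy","precision","recall","fmeasure","mcc"
1,98.88,96.43,87.1,91.53,91.06
2,99.33,100,96.39,98.16,97.78
3,100,100,100,100,100
4,98.88,96.81,97.85,97.33,96.62
5,99.55,98.63,98.63,98.63,98.36
6,98.88,95.65,98.88,97.24,96.56
7,98.88,77.78,93.33,84.85,84.65
8,98.66,90.32,90.32,90.32,89.6
9,99.33,94.44,89.47,91.89,91.58
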