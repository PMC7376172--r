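residue,PH,PE,PC
A,1.41,0.75,0.77
C,0.79,1.41,0.95
D,0.89,0.55,1.37
E,1.38,0.68,0.84
F,0.99,1.42,0.77
G,0.49,0.65,1.68
H,0.90,0.97,1.11
I,1.02,1.67,0.58
K,1.14,0.80,0.99
L,1.28,1.12,0.67
M,1.20,1.01,0.80
N,0.77,0.64,1.43
P,0.54,0.44,1.76
Q,1.25,0.79,0.89
R,1.19,0.88,0.89
S,0.80,0.89,1.25
T,0.76,1.25,1.08
V,0.85,1.87,0.62
W,1.06,1.34,0.74
Y,0.97,1.42,0.78
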