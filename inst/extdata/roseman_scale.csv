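residue,hydropathy
A,0.39
R,-3.95
N,-1.91
D,-3.81
C,0.25
Q,-1.30
E,-2.91
G,0.00
H,-0.64
I,1.82
L,1.82
K,-2.77
M,0.96
F,2.27
P,0.99
S,-1.24
T,-1.00
W,2.13
Y,1.47
V,1.30
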