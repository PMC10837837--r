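# background amino-acid composition of a typical bacterial proteome, table version 1.0
aa,freq
A,0.089
R,0.055
N,0.039
D,0.054
C,0.011
Q,0.039
E,0.061
G,0.074
H,0.021
I,0.071
L,0.095
K,0.059
M,0.024
F,0.042
P,0.039
S,0.059
T,0.054
W,0.012
Y,0.031
V,0.071
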