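# Fauchere-Pliska (1983) octanol/water hydrophobicity scale (pi values).
# The default scale for mean hydrophobicity <H> and hydrophobic moment muH;
# whole-sequence means on known LCAMPs computed with this scale agree with
# HeliQuest output to 3 decimals.
A 0.310
R -1.010
N -0.600
D -0.770
C 1.540
Q -0.220
E -0.640
G 0.000
H 0.130
I 1.800
L 1.700
K -0.990
M 1.230
F 1.790
P 0.720
S -0.040
T 0.260
W 2.250
Y 0.960
V 1.220
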