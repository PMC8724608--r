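name	kind	mass
G	residue	57.02146
A	residue	71.03711
S	residue	87.03203
P	residue	97.05276
V	residue	99.06841
T	residue	101.04768
C	residue	103.00919
L	residue	113.08406
I	residue	113.08406
N	residue	114.04293
D	residue	115.02694
Q	residue	128.05858
K	residue	128.09496
E	residue	129.04259
M	residue	131.04049
H	residue	137.05891
F	residue	147.06841
R	residue	156.10111
Y	residue	163.06333
W	residue	186.07931
p	residue	113.04767000000001
Hex	glycan	162.05282
HexNAc	glycan	203.07937
dHex	glycan	146.05791
Pent	glycan	132.04226
proton	constant	1.0072765
water	constant	18.010565
oxidation	modification	15.99491
deamidation	modification	0.98402
dehydro	modification	-1.00783
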