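residue	mass	lambda	sigma
A	71.08	0.72973	0.504
R	156.19	0.00000	0.656
N	114.10	0.43243	0.568
D	115.09	0.37838	0.558
C	103.14	0.59459	0.548
Q	128.13	0.51351	0.602
E	129.12	0.45946	0.592
G	57.05	0.64865	0.450
H	137.14	0.51351	0.608
I	113.16	0.97297	0.618
L	113.16	0.97297	0.618
K	128.17	0.51351	0.636
M	131.20	0.83784	0.618
F	147.18	1.00000	0.636
P	97.12	1.00000	0.556
S	87.08	0.59459	0.518
T	101.10	0.67568	0.562
W	186.21	0.94595	0.678
Y	163.18	0.86486	0.646
V	99.07	0.89189	0.586
pS	167.06	0.45000	0.620
pT	181.08	0.48000	0.640
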