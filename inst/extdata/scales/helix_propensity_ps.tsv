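# name: helix_propensity
# units: kcal/mol
# nterm: 0
# cterm: 0
# Pace & Scholtz (1998) helix propensities: free-energy cost of helix
# formation relative to Ala (0). Higher values are less helix-favorable;
# Pro (3.16) and Gly (1.0) are the strongest helix breakers.
residue	value
A	0.00
L	0.21
R	0.21
M	0.24
K	0.26
Q	0.39
E	0.40
I	0.41
W	0.49
S	0.50
Y	0.53
F	0.54
H	0.61
V	0.61
N	0.65
T	0.66
C	0.68
D	0.69
G	1.00
P	3.16
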