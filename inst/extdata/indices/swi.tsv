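# Solubility-Weighted Index (SWI): per-residue solubility weights from the
# arithmetic-mean model of Bhandari, Gardner & Lim (2020), Bioinformatics
# 36(18):4691-4698. High value = favours solubility (note: opposite sense
# to the two hydrophobicity scales; inverted after normalization before use
# as a loss). Weights rounded to 4 decimal places; residue order is the
# fixed one-letter alphabetical convention used throughout this package.
# residue	value
A	0.8356
C	0.5479
D	0.9565
E	0.9199
F	0.5850
G	0.7997
H	0.8948
I	0.6784
K	0.9267
L	0.6554
M	0.6297
N	0.8597
P	0.8235
Q	0.7894
R	0.7712
S	0.7441
T	0.8097
V	0.7358
W	0.6375
Y	0.6113
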