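# Per-residue tables used by the physicochemical property calculations.
# mw: average (not monoisotopic) molecular weight of the free amino acid, Da
#     (subtract one water per peptide bond when summing).
# kd: Kyte-Doolittle hydropathy value.
aa	mw	kd
A	89.0932	1.8
R	174.2010	-4.5
N	132.1179	-3.5
D	133.1027	-3.5
C	121.1582	2.5
Q	146.1445	-3.5
E	147.1293	-3.5
G	75.0666	-0.4
H	155.1546	-3.2
I	131.1729	4.5
L	131.1729	3.8
K	146.1876	-3.9
M	149.2113	1.9
F	165.1891	2.8
P	115.1305	-1.6
S	105.0926	-0.8
T	119.1192	-0.7
W	204.2252	-0.9
Y	181.1885	-1.3
V	117.1463	4.2
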