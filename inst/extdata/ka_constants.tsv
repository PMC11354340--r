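# Gapped Karlin-Altschul parameters as reported by NCBI tblastn 2.17
# (comp_based_stats 0). gap_open/gap_extend NA = ungapped (ideal) values.
matrix	gap_open	gap_extend	lambda	K	H
PAM30	NA	NA	0.342	0.273	1.96
PAM250	NA	NA	0.230	0.0900	0.334
BLOSUM45	NA	NA	0.230	0.0911	0.303
BLOSUM90	NA	NA	0.338	0.188	0.852
PAM30	10	1	0.309	0.150	0.880
BLOSUM90	11	1	0.302	0.0930	0.390
PAM30	8	1	0.270	0.0720	0.400
BLOSUM90	9	1	0.265	0.0440	0.200
PAM30	5	2	0.264	0.0790	0.450
BLOSUM90	6	2	0.259	0.0480	0.220
PAM30	14	2	0.337	0.270	1.62
PAM30	15	3	0.339	0.280	1.70
BLOSUM90	9	2	0.310	0.120	0.460
BLOSUM90	8	2	0.300	0.0990	0.390
BLOSUM45	19	1	0.205	0.0400	0.110
PAM250	21	1	0.205	0.0450	0.110
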