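# Synthetic non-canonical amino-acid property extension
# (AAindexNC-style: three-letter code, accession, value; synthetic values).
code	accession	value
HYP	KARS160108	-2.044
MSE	KARS160108	-0.464
MLY	KARS160108	0.256
CSO	KARS160108	0.681
PCA	KARS160108	-0.169
HYP	PTIO830101	1.079
MLY	PTIO830101	-0.532
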