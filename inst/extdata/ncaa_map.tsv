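# Mapping of frequently occurring non-canonical amino acid three-letter
# codes to the one-letter code of their canonical counterpart.
# Extensible: users may supply their own table to parseStructure().
code	one_letter	counterpart
MSE	M	MET
PCA	E	GLU
MLY	K	LYS
MLZ	K	LYS
M3L	K	LYS
KCX	K	LYS
LLP	K	LYS
HYP	P	PRO
CSO	C	CYS
OCS	C	CYS
CSD	C	CYS
CME	C	CYS
CSX	C	CYS
CAS	C	CYS
SEP	S	SER
TPO	T	THR
PTR	Y	TYR
MLE	L	LEU
FME	M	MET
ALY	K	LYS
DDZ	A	ALA
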