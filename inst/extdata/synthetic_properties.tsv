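# Synthetic stand-in physicochemical property tables.
# Values are NOT the published AAindex scales; they are fixed synthetic
# numbers keyed by the accession names used in the descriptor catalog,
# shipped so catalogs and tests run without external databases.
accession	code	value
KARS160108	ALA	0.44
KARS160108	ARG	0.969
KARS160108	ASN	0.761
KARS160108	ASP	0.172
KARS160108	CYS	0.425
KARS160108	GLN	2.223
KARS160108	GLU	-0.132
KARS160108	GLY	1.16
KARS160108	HIS	0.349
KARS160108	ILE	-0.388
KARS160108	LEU	0.505
KARS160108	LYS	1.397
KARS160108	MET	0.681
KARS160108	PHE	1.21
KARS160108	PRO	-1.474
KARS160108	SER	0.265
KARS160108	THR	1.112
KARS160108	TRP	0.051
KARS160108	TYR	-0.544
KARS160108	VAL	0.204
MUNV940102	ALA	-1.343
MUNV940102	ARG	0.73
MUNV940102	ASN	1.172
MUNV940102	ASP	0.957
MUNV940102	CYS	1.558
MUNV940102	GLN	-0.688
MUNV940102	GLU	-1.213
MUNV940102	GLY	-0.947
MUNV940102	HIS	1.048
MUNV940102	ILE	0.646
MUNV940102	LEU	-0.862
MUNV940102	LYS	0.162
MUNV940102	MET	0.042
MUNV940102	PHE	-0.221
MUNV940102	PRO	0.691
MUNV940102	SER	0.671
MUNV940102	THR	0.676
MUNV940102	TRP	-0.775
MUNV940102	TYR	1.509
MUNV940102	VAL	0.499
MUNV940103	ALA	1.841
MUNV940103	ARG	0.637
MUNV940103	ASN	-0.25
MUNV940103	ASP	0.109
MUNV940103	CYS	-0.109
MUNV940103	GLN	-1.778
MUNV940103	GLU	-0.491
MUNV940103	GLY	1.919
MUNV940103	HIS	0.042
MUNV940103	ILE	-0.657
MUNV940103	LEU	0.274
MUNV940103	LYS	1.775
MUNV940103	MET	-0.789
MUNV940103	PHE	0.95
MUNV940103	PRO	0.535
MUNV940103	SER	-0.221
MUNV940103	THR	1.654
MUNV940103	TRP	1.773
MUNV940103	TYR	0.373
MUNV940103	VAL	0.261
PTIO830101	ALA	-0.872
PTIO830101	ARG	0.213
PTIO830101	ASN	2.678
PTIO830101	ASP	-0.202
PTIO830101	CYS	0.085
PTIO830101	GLN	1.481
PTIO830101	GLU	-1.078
PTIO830101	GLY	1.589
PTIO830101	HIS	0.752
PTIO830101	ILE	2.553
PTIO830101	LEU	-2.89
PTIO830101	LYS	-0.338
PTIO830101	MET	-1.104
PTIO830101	PHE	1.053
PTIO830101	PRO	0.167
PTIO830101	SER	0.191
PTIO830101	THR	0.147
PTIO830101	TRP	1.071
PTIO830101	TYR	0.391
PTIO830101	VAL	0.669
MIYS990102	ALA	-1.433
MIYS990102	ARG	0.576
MIYS990102	ASN	-1.991
MIYS990102	ASP	1.945
MIYS990102	CYS	-0.695
MIYS990102	GLN	0.008
MIYS990102	GLU	0.319
MIYS990102	GLY	1.155
MIYS990102	HIS	1.445
MIYS990102	ILE	-1.574
MIYS990102	LEU	1.272
MIYS990102	LYS	0.313
MIYS990102	MET	0.654
MIYS990102	PHE	-2.079
MIYS990102	PRO	-1.209
MIYS990102	SER	0.041
MIYS990102	THR	-0.411
MIYS990102	TRP	0.776
MIYS990102	TYR	0.466
MIYS990102	VAL	1.257
PONP800104	ALA	0.579
PONP800104	ARG	0.976
PONP800104	ASN	1.946
PONP800104	ASP	1.647
PONP800104	CYS	-1.585
PONP800104	GLN	0.343
PONP800104	GLU	-0.894
PONP800104	GLY	-2.541
PONP800104	HIS	-1.408
PONP800104	ILE	-3.039
PONP800104	LEU	-1.107
PONP800104	LYS	0.025
PONP800104	MET	0.634
PONP800104	PHE	0.01
PONP800104	PRO	0.618
PONP800104	SER	0.25
PONP800104	THR	1.12
PONP800104	TRP	0.113
PONP800104	TYR	0.356
PONP800104	VAL	-0.76
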