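ligand	resid	resno	energy_kcal_mol
daridorexant	GLU	204	-25.18
daridorexant	HIS	216	-16.04
daridorexant	ASN	318	-6.04
daridorexant	PHE	340	-5.13
daridorexant	GLN	179	-4.74
daridorexant	PHE	220	-3.83
daridorexant	GLN	126	-3.23
daridorexant	ILE	314	-3.01
daridorexant	PRO	123	-2.33
daridorexant	LEU	317	-2.26
daridorexant	ASP	203	-1.57
daridorexant	ARG	322	-1.26
daridorexant	HIS	344	-1.00
daridorexant	LYS	321	-0.68
lemborexant	HIS	344	-5.43
lemborexant	VAL	130	-4.93
lemborexant	TYR	311	-4.54
lemborexant	GLN	126	-4.38
lemborexant	ILE	314	-4.00
lemborexant	ASN	318	-3.81
lemborexant	VAL	347	-2.07
lemborexant	TYR	244	-1.77
lemborexant	ALA	127	-1.66
lemborexant	SER	315	-1.63
lemborexant	THR	223	-1.63
lemborexant	TYR	348	-1.59
lemborexant	LYS	321	-1.56
lemborexant	GLU	204	-1.44
lemborexant	VAL	134	-1.17
suvorexant	HIS	344	-5.79
suvorexant	GLN	126	-4.52
suvorexant	PRO	123	-3.65
suvorexant	VAL	128	-2.78
suvorexant	ASN	318	-2.49
suvorexant	PHE	220	-2.41
suvorexant	ILE	314	-2.39
suvorexant	TRP	112	-2.27
suvorexant	MET	183	-1.96
suvorexant	SER	103	-1.92
suvorexant	GLU	204	-1.60
suvorexant	ILE	122	-1.54
suvorexant	THR	223	-1.44
suvorexant	TYR	311	-1.40
suvorexant	ASP	203	-0.98
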