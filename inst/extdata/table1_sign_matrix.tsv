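metabolite_id	compartments	exp	DDC	PKM	UROD	CPOX	HMBS	FECH	GPX7	TXNRD1	SPTLC1	SCD	RPIA	GYS1	ALPL	ASAH1	SGPL1	PAFAH1B1
Leucine	c;m	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	-1	-1	+1
Choline	c;n	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	+1	-1	-1
Pantothenic_acid	c	-1	-1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	+1	+1	+1
L-Acetylcarnitine	c;m;x	-1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	+1	+1
Glutathione	c;m	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	-1	+1	-1	-1	-1
L-Tryptophan	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	+1	+1	+1
L-Glutamine	c;m	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	-1	-1	-1	+1
S-Formylglutathione	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1
L-Cysteine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	-1	-1	+1
Phenylalanine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1
L-Proline	c;m	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	+1	-1	-1	-1	-1
Hydroxybutyrylcarnitine	c	-1	-1	-1	-1	-1	-1	-1	-1	+1	-1	-1	-1	+1	+1	-1	-1	+1
L-Alanine	c;m;x	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	-1	+1	+1	+1
AMP	c;m;r;x	+1	-1	+1	+1	+1	+1	+1	-1	+1	-1	-1	-1	-1	+1	-1	+1	-1
Creatine	c	+1	+1	-1	+1	-1	-1	-1	+1	+1	-1	+1	+1	-1	+1	-1	+1	-1
Adenine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	-1	+1	-1	+1
L-Methionine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	+1	-1	+1
Biotin	c;m;n	-1	-1	-1	-1	-1	-1	-1	-1	+1	-1	-1	-1	-1	-1	-1	-1	-1
Cysteinylglycine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	-1	-1	+1	-1	-1	+1
L-Glutamic_acid	c;m	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	+1	-1
L-Valine	c;m	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	+1	+1	+1
L-Carnitine	c;m;x	-1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	-1	-1	+1	+1	+1
Dimethylglycine	c;m	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	-1	+1	-1	+1
L-Histidine	c;m	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	+1
Adenosine	c;m	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	-1	+1	-1	+1
Valerylcarnitine	c	-1	-1	+1	-1	-1	-1	-1	-1	+1	+1	-1	+1	+1	-1	+1	-1	+1
Betaine	c	-1	+1	-1	+1	+1	+1	+1	+1	+1	+1	-1	+1	-1	-1	+1	-1	+1
Hexanoylcarnitine	c;x	-1	0	0	0	0	0	0	0	0	+1	0	0	0	0	0	0	0
5-Methyltetrahydrofolic_acid	c	-1	+1	+1	-1	+1	+1	+1	+1	-1	+1	-1	+1	+1	-1	+1	-1	+1
Niacinamide	c	-1	0	0	+1	0	0	0	0	0	0	0	+1	0	0	0	0	+1
L-Threonine	c	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	-1	-1	+1	+1	+1
2-Aminomuconic_semialdehyde	c	-1	0	0	0	0	0	0	0	+1	+1	+1	+1	+1	+1	0	0	0
Homovanillic_acid	m	-1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1	+1
Cholesterol	c;l;m;r	+1	+1	-1	+1	+1	+1	+1	+1	-1	+1	+1	+1	-1	-1	-1	+1	-1
Guanine	c	+1	+1	-1	+1	+1	+1	+1	+1	+1	+1	-1	+1	+1	+1	-1	+1	-1
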