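metabolite_id	sign	source_label
Leucine	+1	experiment
Choline	+1	experiment
Pantothenic_acid	-1	experiment
L-Acetylcarnitine	-1	experiment
Glutathione	+1	experiment
L-Tryptophan	+1	experiment
L-Glutamine	+1	experiment
S-Formylglutathione	+1	experiment
L-Cysteine	+1	experiment
Phenylalanine	+1	experiment
L-Proline	+1	experiment
Hydroxybutyrylcarnitine	-1	experiment
L-Alanine	+1	experiment
AMP	+1	experiment
Creatine	+1	experiment
Adenine	+1	experiment
L-Methionine	+1	experiment
Biotin	-1	experiment
Cysteinylglycine	+1	experiment
L-Glutamic_acid	+1	experiment
L-Valine	+1	experiment
L-Carnitine	-1	experiment
Dimethylglycine	+1	experiment
L-Histidine	+1	experiment
Adenosine	+1	experiment
Valerylcarnitine	-1	experiment
Betaine	-1	experiment
Hexanoylcarnitine	-1	experiment
5-Methyltetrahydrofolic_acid	-1	experiment
Niacinamide	-1	experiment
L-Threonine	+1	experiment
2-Aminomuconic_semialdehyde	-1	experiment
Homovanillic_acid	-1	experiment
Cholesterol	+1	experiment
Guanine	+1	experiment
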