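metabolite_id	sign	source_label
glucose	+1	warburg
pyruvate	+1	warburg
lactate	+1	warburg
alanine	+1	warburg
glutamine	+1	warburg
glutamate	+1	warburg
alpha-ketoglutarate	+1	warburg
citrate	+1	warburg
isocitrate	+1	warburg
succinyl-CoA	+1	warburg
succinate	+1	warburg
fumarate	+1	warburg
malate	+1	warburg
oxaloacetate	-1	warburg
acetyl-CoA	-1	warburg
ATP	+1	warburg
NADH	+1	warburg
aspartate	-1	warburg
serine	+1	warburg
glycine	+1	warburg
ribose-5-phosphate	+1	warburg
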