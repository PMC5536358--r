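exchange_id	lower	upper
EX_glc	-10	0
EX_bilirubin_direct	1.7	8.55
EX_bilirubin_indirect	0	6.84
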