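gene	sr_experiment
DDC	0.75
PKM	0.556
UROD	0.694
CPOX	0.639
HMBS	0.639
FECH	0.639
GPX7	0.5
TXNRD1	0.556
SPTLC1	0.583
SCD	0.583
RPIA	0.444
GYS1	0.417
ALPL	0.361
ASAH1	0.417
SGPL1	0.417
PAFAH1B1	0.472
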