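gene	bestkeeper	normfinder	genorm	deltact	consensus_published
PPP6R1	2	1	1	1	1.19
CCDC97	1	2	2	2	1.86
ACTB	6	3	5	3	2.28
EPHA2	4	4	3	4	4.00
B2M	5	6	6	5	5.48
GAPDH	3	7	4	6	5.96
EHD3	7	5	7	7	6.44
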