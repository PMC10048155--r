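gene	forward_seq	reverse_seq	forward_start	reverse_end	declared_bp	annealing_temp_c
PPP6R1	ATTGTCCAGCGGCTCATCGAGC	GGGACTGGGACGCATTGGAATG	840	912	73	67
EHD3	CTTTGGCAATGCCTTCTTGAAC	AGAGAGGATCCCTGGAGTGTCG	1121	1217	97	62
CCDC97	TGGTGACCACCGAGCAGACTTC	TGCTCGTCGCTGAAGTACTCGC	501	647	147	71
EPHA2	TGCCCATCGGTCAGTGTCTGTG	GTGTGCAGGGCACTCCAAACAG	764	888	125	71
GAPDH	TGGCATCGTGGAGGGACTCATG	ATCGCGCCACATCTTCCCAGAG	552	642	91	72
ACTB	CATCGCCGACAGGATGCAGAAG	GCTGGAAGGTGGACAATGAGGC	924	1060	137	72
B2M	CTGCTGCTGTGGTAGCTATGGC	AAACCTGAACCTTCGGAACACG	14	118	105	65
FABP5	GAAGATGGCGCTTGGTGGAGAG	AATCTGGTTTGGCCATTGCACC	103	204	102	68
RUNX2	CTGCTGAGCTCCGAAATGCCTC	AACTCTTGCCTCGTCCACTCCG	847	942	96	69
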