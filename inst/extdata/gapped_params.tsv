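matrix	gip	gep	lambda	K
BLOSUM62	13	1	0.292	0.071
BLOSUM62	12	1	0.283	0.059
BLOSUM62	11	1	0.267	0.041
BLOSUM62	10	1	0.243	0.024
BLOSUM62	9	1	0.206	0.010
BLOSUM62	11	2	0.297	0.082
BLOSUM62	10	2	0.291	0.075
BLOSUM62	9	2	0.279	0.058
BLOSUM62	8	2	0.264	0.045
BLOSUM62	7	2	0.239	0.027
BLOSUM62	6	2	0.201	0.012
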