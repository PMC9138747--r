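peptide	residue_index	residue_code	state	fraction
GAG	1	A	pPII	0.8
GAG	1	A	beta	0.1
GAG	1	A	igamma_typeII	0.03
GAG	1	A	rh	0.03
GAG	1	A	lh	0.04
GFG	1	F	pPII	0.45
GFG	1	F	beta	0.45
GFG	1	F	igamma_typeII	0
GFG	1	F	rh	0.05
GFG	1	F	lh	0.05
GAFG	1	A	pPII	0.8
GAFG	1	A	beta	0.05
GAFG	1	A	igamma_typeII	0
GAFG	1	A	rh	0
GAFG	1	A	lh	0.15
GAFG	2	F	pPII	0.37
GAFG	2	F	beta	0.57
GAFG	2	F	igamma_typeII	0
GAFG	2	F	rh	0
GAFG	2	F	lh	0.06
GFAG	1	F	pPII	0.61
GFAG	1	F	beta	0.32
GFAG	1	F	igamma_typeII	0
GFAG	1	F	rh	0
GFAG	1	F	lh	0.06
GFAG	2	A	pPII	0.64
GFAG	2	A	beta	0.27
GFAG	2	A	igamma_typeII	0
GFAG	2	A	rh	0
GFAG	2	A	lh	0.07
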