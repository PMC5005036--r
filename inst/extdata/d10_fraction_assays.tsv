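fraction	description	protein_ug	total_intensity
S1	post-nuclear supernatant	109000	2.63e10
S2	low-speed supernatant	100000	0.35e10
P2	dense membranes	36400	2.56e10
M3	antibody-bead bound	2680	0.34e10
S6	cytoplasm	29200	0.32e10
P6	membranes	984	0.28e10
S7	detergent-soluble membranes	1037	1.13e10
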