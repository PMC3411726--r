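adduct_class	rank	site_class
quinone	1	Cys_sidechain
quinone	2	N_terminus
quinone	3	Lys_sidechain
quinone	4	His_sidechain
epoxide	1	Cys_sidechain
epoxide	2	His_sidechain
epoxide	3	Lys_sidechain
epoxide	4	N_terminus
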