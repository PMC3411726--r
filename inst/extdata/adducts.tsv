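name	formula	class	symbol	targets	note
NO	C10H8O	epoxide	#	Cys_sidechain,Lys_sidechain,His_sidechain,N_terminus	naphthalene 1,2-epoxide; SN2 ring-opening addition
NDO	C10H10O3	epoxide	ψ	Cys_sidechain,Lys_sidechain,His_sidechain,N_terminus	naphthalene diol epoxide; addition retains both diol oxygens
NQ12	C10H6O2	quinone	†	Cys_sidechain,Lys_sidechain,His_sidechain,N_terminus	1,2-naphthoquinone; Michael addition, hydroquinone-form delta
NQ14	C10H6O2	quinone	°	Cys_sidechain,Lys_sidechain,His_sidechain,N_terminus	1,4-naphthoquinone; Michael addition, hydroquinone-form delta
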