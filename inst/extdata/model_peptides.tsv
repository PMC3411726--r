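peptide	c_terminus	nucleophile	note
GRGDSPC	free_acid	Cys	fibronectin cell-attachment motif plus C-terminal cysteine
YGGFLRKR	free_acid	Lys	alpha-neo-endorphin fragment; Lys flanked by arginines
DYKDDDDK	free_acid	Lys	FLAG epitope; internal and C-terminal lysines
DASFHSWG-NH2	amide	His	leucokinin IV, C-terminally amidated
EFYAPWCG	free_acid	Cys	protein disulfide isomerase fragment
EIVRDIKE	free_acid	Lys	actin fragment; Lys adjacent to glutamate
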