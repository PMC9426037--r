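gene	pattern	pattern_type	oncokb_level	escat_tier
PIK3CA	p.H1047R	exact	1	IA
PIK3CA	p.E545K	exact	1	IA
PIK3CA	p.E542K	exact	1	IA
PIK3CA	542-546	range	2	IB
PIK3CA	1043-1049	range	2	IB
PIK3CA	any_oncogenic_mutation	class	2	IIA
ERBB2	p.L755S	exact	3A	IIB
ERBB2	p.V777L	exact	3A	IIB
ERBB2	755-781	range	3A	IIB
ERBB2	amplification	class	1	IA
ESR1	p.D538G	exact	3A	IIA
ESR1	p.Y537S	exact	3A	IIA
ESR1	536-538	range	3A	IIA
AKT1	p.E17K	exact	3A	IIB
BRCA2	any_oncogenic_mutation	class	1	IA
BRCA1	any_oncogenic_mutation	class	1	IA
PALB2	any_oncogenic_mutation	class	3A	IIB
PTEN	deletion	class	4	IIIA
MET	amplification	class	2	IIB
FGFR1	amplification	class	3A	IIIA
CCND1	amplification	class	4	IV
MYC	amplification	class	none	IV
KRAS	amplification	class	4	IIIA
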