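label	class	years_per_mutation	citation
coding.a	coding_substitution	5140	Mishmar et al. 2003, whole coding-region substitution rate
coding.b	coding_substitution	4610	Kivisild et al. 2006, coding-region substitution rate
syn.c	synonymous_transition	6764	Kivisild et al. 2006, synonymous transition rate
syn.b	synonymous_transition	7650	companion synonymous rate of calibration b (back-derived; confirm against source)
syn.d	synonymous_transition	7884	Soares et al. 2009, synonymous clock
syn.e	synonymous_transition	7990	Loogväli et al. 2009, synonymous transitions (back-derived; confirm against source)
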