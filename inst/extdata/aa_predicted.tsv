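# In-silico prediction of amino-acid biosynthetic pathway completeness per strain
# (+ complete pathway predicted, - incomplete). Footnote marks of the source table
# are carried in the note column and do not affect the symbols.
group	trait	m4-4	m2-6	p1.1.43	note
a-Keto-glutarate	E	+	+	+	.
a-Keto-glutarate	Q	+	+	+	.
Urea cycle	P	+	+	+	.
Urea cycle	R	-*	-*	-*	incomplete urea cycle
3-P-glycerate	S	-*a	-*	-*	m4-4 has alternative serine route via L-serine ammonia-lyase
3-P-glycerate	G	+	+	+	.
3-P-glycerate	C	+	+	+	.
Oxalacetate	D	+	+	+	.
Oxalacetate	N	+	+	+	.
Oxalacetate	M	-*a	-*a	-*a	methylthioadenosine salvage route present
Oxalacetate	T	+	+	+	.
Oxalacetate	K	+	+	+	.
Pyruvate	A	+	+	+	.
Pyruvate	V	-**	-**	-**	pyruvate pathway eroded
Pyruvate	I	-**	-**	-**	pyruvate pathway eroded
Pyruvate	L	-**	-**	-**	pyruvate pathway eroded
PEP and Erythrose 4-P	W	+	+	+	.
PEP and Erythrose 4-P	F	+	+	+	.
PEP and Erythrose 4-P	Y	+	+	+	.
Ribose 5-P	H	+	+	+	.
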