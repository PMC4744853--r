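# Growth evaluation of amino-acid auxotrophies per strain (+ growth without the amino acid, - auxotrophic).
# The source table's printed total row reads 7 / 11 / 7; the p1.1.43 column's "-" entries count to 8,
# matching the accompanying text ("p1.1.43 (8)").
group	trait	m4-4	m2-6	p1.1.43
a-Keto-glutarate	E	-	-	-
a-Keto-glutarate	Q	+	+	+
Urea cycle	P	+	-	+
Urea cycle	R	-	-	-
3-P-glycerate	S	+	-	-
3-P-glycerate	G	+	+	+
3-P-glycerate	C	+	-	+
Oxalacetate	D	+	-	+
Oxalacetate	N	+	+	+
Oxalacetate	M	+	+	+
Oxalacetate	T	-	+	-
Oxalacetate	K	+	-	+
Pyruvate	A	+	+	+
Pyruvate	V	-	-	-
Pyruvate	I	-	-	-
Pyruvate	L	-	-	-
PEP and Erythrose 4-P	W	+	+	+
PEP and Erythrose 4-P	F	-	-	-
PEP and Erythrose 4-P	Y	+	+	+
Ribose 5-P	H	+	+	+
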