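# Phosphorus recycling / scavenging / storage gene repertoires per strain.
# The alkaline phosphatase (phoA) row is a three-level regulation trait
# (Constitutive / Induce / -) and is excluded from binary concordance.
group	trait	m4-4	m2-6	p1.1.43
Recycling	Alkaline phosphodiesterase I	+	+	+
Recycling	2',3' cyclic nucleotide transferase (yfkN)	+	+	+
Recycling	Alkaline phosphatase (phoA)	Constitutive	-	Induce
Scavenging	Phosphonoacetaldehyde dehydrogenase (phnY)	+	+	+
Scavenging	Phn transporters (phnCDE1E2)	-	+	-
Storage	Polyphosphate kinase ppK	+	+	+
Storage	Exopolyphosphatase	+	+	+
Storage	Teichoic acids biosynthesis genes	-	-	-
Storage	sqd1	+	+	+
Storage	sqdX	+	+	+
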