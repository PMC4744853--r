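---
title: "Methods: strain-level comparative genomics with microevo"
author: "microevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level comparative genomics with microevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microevo)
```

# Scope

`microevo` analyses microevolution — genomic change below the species
level — among conspecific bacterial strains. Given assembled genomes
with gene annotations, it partitions the pangenome into core, shared
accessory and strain-specific gene families, estimates genome
relatedness by fragment-based average nucleotide identity (ANI), calls
genomic-island candidates from GC anomalies, weighs three independent
lines of evidence for horizontal gene transfer (HGT), detects marker
protein families with log-odds profiles, and confronts genotype-derived
predictions with phenotype tables. A synthetic clade generator with
planted ground truth makes every stage testable without any external
data, which is how the package validates itself.

# The pangenome partition

Orthology is established by the bidirectional best hit (BBH) criterion:
two genes in different genomes are orthologs when each is the other's
highest-scoring match. Protein pairs are aligned by Smith–Waterman
local alignment under BLOSUM62 with affine gaps (open 11, extend 1; a
gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$). Raw
scores are converted to bits with fixed Karlin–Altschul constants
($\lambda = 0.267$, $K = 0.041$, the gapped BLOSUM62 defaults),

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with $m$ the subject-proteome residue total and $n$ the query length.
The constants are configuration, not estimates: the e-value acts as a
filter (default $E \le 10^{-6}$), not a calibrated statistic. A BBH
additionally requires that the aligned span covers at least 60% of both
sequences in both directions — the strictest reading of a "mutual
coverage of 60%" rule; both thresholds are exposed as arguments.

All-vs-all comparison is seeded by shared amino-acid 4-mers (subjects
sharing at least 8 distinct 4-mers with the query are rescored by full
dynamic programming), mirroring the word-seeding of standard search
tools; small problems are compared exhaustively, and `prefilter =
FALSE` forces exhaustive comparison at any size.

Families are connected components of the union BBH graph across all
genome pairs. Components are deliberately not required to be cliques:
the BBH methodology leaves this open, components are the common
convention, and the decision is isolated in `buildFamilies()`. When a
component holds more than one gene from a strain, the gene with the
highest summed bit score to the other members keeps the seat and the
rest are re-seated as strain-specific singletons. A family is *core*
when every strain is represented, *specific* with exactly one strain,
*shared* otherwise. The headline statistic, the core fraction, is the
core family count divided by the mean per-genome CDS count — with the
published counts (2,893 core; CDS 3,556/3,500/3,530) this is the 82%
worked example, with the 18% complement being the per-genome accessory
fraction.

Synteny conservation between two genomes is the fraction of adjacent
core-gene pairs of one genome whose family images are adjacent (either
orientation) in the other; it is undefined (an error) when no contig
carries two core genes.

# Fragment-based ANI

The query genome is cut into consecutive, non-overlapping 1,020-nt
fragments (the defining constant of the fragment-mapping ANI flavour;
trailing remainders are discarded rather than padded so per-fragment
statistics stay identically distributed). Each fragment is located in
the subject by exact 18-mer seeds taken at five offsets on both
strands, then rescored by full local dynamic programming (+1/−1
match/mismatch, gap open 2 extend 1) in a ±60-bp window around the
seeded position. A fragment is retained when its best hit has identity
≥ 30% over an aligned length ≥ 70% of the fragment; identity counts
identical positions over all alignment columns, gap columns included —
a conservative dialect choice whose effect is well inside the ±0.2
calibration tolerance. The directed ANI is the mean identity of
retained fragments (undefined, not zero, when nothing is retained);
the symmetric ANI averages the two directions, which makes it exactly
symmetric. On simulated pairs with no indels the symmetric ANI tracks
the planted per-site identity to within 0.2 points at megabase scale;
terminal-mismatch trimming by the local alignment biases it upward by
well under 0.05 points.

# GC-anomaly genomic islands

GC is computed per 5-kb window every 500 bp and standardised against
the mean and standard deviation of all windows of the *same* genome —
each genome is its own compositional background. Islands are maximal
runs of windows with $z \le -3$ (a low-GC scan by default; an absolute
mode exists), merged across gaps up to twice the step, and kept at a
minimum span of 8 kb; the mean GC of a call is recomputed over the
exact final span. These defaults make a 25-kb island 6 GC points below
a 38% background unmissable while 100 background-only genomes yield no
calls. Two caveats are documented rather than hidden: island calls are
quantised to window boundaries (expect up to one window of boundary
jitter), and because the window population includes the island itself,
the window standard deviation is inflated when anomalous sequence is
more than a few percent of the genome — island calling is designed for
islands that are a small minority of the genome, as they are in real
assemblies.

Context evidence is attached in two forms. Mobile-genetic-element
markers are genes within 5 kb of the island whose product annotation
matches a keyword lexicon (integrase, transposase, insertion sequence,
phage, recombinase, and word-boundary "IS" so that `IS643` counts but
"island" does not). Flanking direct repeats are exact maximal repeats
with one copy wholly inside each 2-kb margin immediately outside the
island span; exactness keeps the oracle trivial, and approximate
repeats are out of scope.

# HGT inference

A locus is judged on three independent signals:

* **Composition** — it lies in a called island whose GC deviates from
  the genome by at least 4 points (configurable).
* **Context** — the island carries at least one MGE marker or flanking
  repeat pair.
* **Phylogeny** — in its gene tree, the focal taxon's minimal sister
  clade with bootstrap support ≥ 70 shares no taxon with its sister
  clade in the species tree pruned to the gene-tree leaf set.

The verdict is *supported* with at least two signals, *partial* with
one, *none* otherwise — a deterministic function of the three booleans,
enforced by the class validity.

Gene trees are built by neighbor joining on model-corrected distances
(p, Poisson, or Jukes–Cantor nucleotide distances computed over
pairwise non-gap sites; saturated pairs are infinite and must be pruned
first) from a center-star multiple alignment (the center maximises
summed pairwise global scores; pairwise alignments are merged under
"once a gap, always a gap"). Support comes from 100 bootstrap
pseudo-replicates of alignment columns, with each internal edge
labelled by the percentage of replicates containing the same
bipartition. Maximum-likelihood inference is intentionally not used:
at the divergences involved the HGT conclusion rests on topology plus
support, which NJ recovers, and NJ keeps the additive-matrix oracle
exact. Negative NJ branch lengths are clamped to zero with the deficit
moved to the sister branch; taxa are ordered by label before
agglomeration so ties break deterministically.

The 70% support threshold mirrors the conventional reporting cutoff
for bootstrap values; the source methodology does not define how large
a sister displacement must be, so the supported-sister-disjointness
rule above is a documented operationalisation, configurable via
`supportMin`. Trees are unrooted internally; rooting (needed for the
sister walk) uses a caller-named outgroup.

# Profile search for marker families

Marker families (phosphonate transporters, phosphonoacetaldehyde
dehydrogenase, alkaline phosphatase and the like) are detected with
per-column log-odds profiles rather than full profile HMMs: presence/
absence detection of well-conserved families does not need insert
states, and score parity with HMM software is a non-goal. A column
scores amino acid $a$ as

$$s_j(a) = \log_2 \frac{(c_{ja} + \pi\,b_a)/(n_j + \pi)}{b_a}$$

with pseudocount weight $\pi = 1$ and a uniform or seed-derived
background; columns that are half gaps or more are dropped. Scanning
takes the best ungapped placement over all offsets (with a glocal
variant allowing terminal truncation at a minimum overlap of half the
profile). Significance is calibrated per target proteome against
residue-shuffled decoys (composition-matched null): a Gumbel location
and scale are fitted to decoy scores by moment matching and
$E(s) = N\,(1 - e^{-e^{-(s-\mu)/\beta}})$. Decoys shorter than the
profile are excluded from calibration when enough long ones exist,
because truncated placements would inflate the fitted scale. The
default presence cutoff is $E \le 10^{-6}$.

# Trait concordance

Phenotype tables (growth evaluations, phosphorus-source utilization,
gene repertoires) are strain-by-trait matrices over `+`/`-` with trait
group labels; transcriptions of the published tables ship as TSV
fixtures, with footnote marks carried in a comment column that never
affects the symbols. Genotype predictions are pathway-completeness
checks: a trait is predicted `+` iff some alternative requirement set
of gene families is fully present — monotone by construction.
Concordance compares tables cell by cell after name alignment,
excluding NA and non-binary cells (the alkaline-phosphatase regulation
states Constitutive/Induce/`-` are a three-level trait reported but
excluded from binary concordance, since the interesting difference
there is regulation, not presence). One transcription discrepancy is
preserved deliberately: the published total row reads 7 auxotrophies
for strain p1.1.43 while the column's `-` entries count to 8 and the
accompanying text says 8; the package reports 8 and the fixture header
records the printed total.

# The synthetic clade generator

The generator is the package's ground truth and defines its reference
study conditions. Defaults (all exposed in `cladeConfig()`):

* three strains (`m4-4`, `m2-6`, `p1.1.43`) at 1/10 scale: 290 core
  families, 30 two-strain shared families (14/8/8 across the three
  pairs), 12/11/9 strain-specific families — preserving an ~82% core
  fraction and the observed ordering of strain-specific gene counts;
* gene lengths ~N(900, 150) bp as stop-free ORFs (ATG…TAA, bacterial
  code), intergenic spacers uniform on 50–500 bp, one contig;
* background GC 37.97%; the interior-codon base composition is solved
  numerically so that the realized genome GC hits the target despite
  stop-codon rejection and the fixed start/stop codons;
* per-branch substitution probabilities 0.0034069 / 0.0029030 /
  0.0078197, solved in log space so that the pairwise identity
  products equal 0.9937 / 0.9893 / 0.9888 — the calibration surrogate
  for the strains' ANI triplet;
* one 25-kb island in `m2-6` at GC 31.68%, with two MGE marker genes,
  one cargo gene and 20-bp exact direct repeats immediately flanking
  the span.

Substitutions are i.i.d. per site with equal exchange among the three
alternative bases (Jukes–Cantor-like), applied independently per
branch, which keeps expected pairwise identity analytically computable
(`exp(-(x_i + x_j))` for branch retentions). Substitutions that would
create an internal stop codon are re-drawn so genes remain translatable
— this redirects well under 1% of substitutions and does not move the
realized identity measurably. Gene loss excises the gene with its
preceding spacer; gains insert at random intergenic points at a
configurable donor GC; gene order is otherwise preserved, so synteny
is conserved by construction. The generating species tree (a star with
the three branch lengths) is emitted in the manifest and serves as the
species-tree reference at desk scale.

For HGT fixtures, `hgtLocusPanel()` surrounds a cargo gene with four
reference homologs whose genealogy either matches the species tree
(vertical control) or places the focal copy next to a distant donor
lineage (transfer); references are generated by walking the genealogy
away from the observed cargo sequence, which is equivalent to forward
simulation under the reversible equal-rates model.

What the generator does *not* emulate — and hence what passing tests
do not certify about real data: recombination and gene conversion,
rearrangements and inversions (real strain pairs can violate the
high-synteny assumption), indels outside whole-gene gain/loss, codon
usage and amino-acid composition realism, multi-contig draft
fragmentation, and annotation noise (real gene callers disagree, which
is why published family counts are not reproduction targets).

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed `GRanges` throughout, the native
  convention of the underlying infrastructure; GFF3 round-trips
  without conversion and BED output converts at the boundary.
* GC excludes N bases from numerator and denominator; an all-N genome
  reports GC as NA with an explicit warning. N50 is the
  descending-cumulative contig length at half the total, ties toward
  the larger contig.
* A uniform genome (window sd 0) yields all-zero z-scores, not an
  error; contigs shorter than one window are skipped with a message.
* Saturated distances (correction argument ≤ 0) are `Inf` and rejected
  by `njTree()` with instructions to prune.
* The Gumbel e-value uses `-expm1(-exp(-x))` so the right tail stays
  strictly monotone; the left tail saturates at the target count
  within double precision, which is a representation limit, not a
  model statement.
* All randomness in a pipeline run flows from one root seed;
  `generateClade()` and `runPipeline()` are byte-deterministic under a
  fixed configuration.

# Problem sizes used in validation

The shipped validation runs at sizes chosen to exercise the method
while staying desk-scale: the reference clade at 1/10 scale (three
~380-kb genomes, ~330 CDS each), ANI calibration on three simulated
1-Mb pairs, island specificity on 100 background-only 60-kb genomes,
and 100 bootstrap pseudo-replicates for every support value. Unit
tests use smaller clades (15–150 core families) for speed; the
exhaustive alignment oracle runs on sequences up to 12 residues, where
brute-force dynamic programming is still exact and cheap.

# Known limitations

* Island boundary calls are window-quantised and the z-background is
  inflated when anomalous sequence exceeds a few percent of the genome.
* The BBH seed prefilter can miss orthologs below roughly 40% identity
  in fast mode; `prefilter = FALSE` restores exhaustive behaviour.
* E-values for both alignment and profile hits are filters with fixed
  or moment-matched constants, not calibrated significance claims.
* `flagHgt()` needs a rooted frame: supply an outgroup when trees are
  unrooted.
* Real-data pangenome counts depend on the upstream gene caller;
  comparisons should hold annotation constant across strains.
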