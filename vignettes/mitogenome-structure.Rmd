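---
title: "Detecting repeat-mediated recombination and structural variation in plant mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated recombination and structural variation in plant mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The biological problem

Plant mitochondrial genomes are large, repeat-rich and structurally
dynamic.  Dispersed repeat pairs scattered around the circular genome act
as substrates for homologous recombination: crossing over between the two
copies of an *inverted* pair produces an isomeric circle with the
intervening segment flipped, while recombination between *direct* copies
splits the master circle into two subgenomic circles.  These alternative
conformations (ACs) usually coexist with the predominant master
conformation (MC) at low stoichiometry, but they can sweep to fixation
(substoichiometric shifting), so measuring their frequency matters for
understanding mitogenome evolution.

Long reads make this measurable: a read long enough to span a repeat copy
*plus* flanking anchors on both sides witnesses which conformation the
molecule it came from had at that repeat.  The frequency of recombination
at a repeat is then the fraction of informative reads supporting the AC:

$$\hat f = \frac{n_{AC}}{n_{AC} + n_{MC}}.$$

`mitorecomb` implements this pipeline end to end — repeat detection,
conformation construction, read classification and frequency estimation —
together with the comparative layer used across a set of related
mitogenomes: core/variable/specific fragment classification with pan- and
core-genome accumulation curves, a two-step gene presence/absence call,
plastid-derived fragment and ORF detection, and alignment statistics
(supermatrix concatenation, parsimony-informative characters).  A
synthetic-data generator with full ground truth makes every stage
testable without any external data or aligner.

## Coordinate conventions

All coordinates are 0-based, half-open and circular (reduced modulo the
genome length); intervals may wrap the origin.  Percentages are rounded
half-even to two decimals wherever they are printed, so published-style
figures are reproducible bit for bit.

## Repeat detection

`find_repeats()` finds dispersed repeat pairs with exact k-mer seeding
(k = 21) on the doubled sequence — doubling makes the search circular —
for both orientations (the inverted search compares the sequence against
its reverse complement).  Seeds sharing a diagonal are extended
gaplessly: every run of at least 15 consecutive matches is a core, cores
are extended by X-drop (X = 25) on a +1/−1 match/mismatch score, and the
segment ends at the running score maximum.  Segments shorter than
`min_len` (default 50 bp) or below `min_identity` (default 0.95,
identity = matches / alignment columns) are discarded.

Two deliberate choices differ from a literal "extend while identity stays
above threshold" rule:

* **Maximality by score, not by threshold.**  A window-maximality rule
  lets an exact 681 bp repeat absorb ~35 columns of mismatching flank
  while staying above 95% identity, mis-reporting both length and
  identity.  X-drop extension to the score maximum reports the
  high-identity core, which is what the repeat *is*; this is the same
  behaviour as BLAST-style HSP extension.
* **Tandem exclusion by gap.**  A pair is reported only when the circular
  gap between the copies is at least the repeat length (equivalently,
  start-to-start distance ≥ 2 × length).  Directly adjacent copies are
  tandem duplications, not dispersed recombination substrates, and
  near-adjacent copies cannot anchor junction flanks anyway.

Non-ACGT characters never match, so ambiguity only ever lowers identity.
Hits sharing more than half of both copy intervals are merged, keeping
the longest.  Repeat families with more than two copies surface as all
pairwise pairs; they are not clustered.

`classify_repeats()` bins pairs by alignment length — small (< 100 bp),
intermediate (100–1000 bp), large (> 1 kb) — and counts repeat bases over
the *union* of all copy intervals, so overlapping copies are never double
counted; `repeat_fraction()` reports the union as a percent of the
genome.

## Conformations and junction windows

`build_alternative_conformation()` applies one recombination event:

* inverted pair → one circle with the inter-copy segment
  reverse-complemented (an isomer; applying the operation twice restores
  the master circle);
* direct pair → two subgenomic circles of lengths $d$ and $L - d$, where
  $d$ is the start-to-start distance (total length is always conserved).

When the two copies are not identical the crossover position inside the
repeat is unidentifiable from reads, so copy 1's sequence is written at
the novel junctions; at ≥ 95% copy identity this costs at most a few
mismatches against reads from the other allele, far inside the
classification margin.

`extract_junctions()` reduces each conformation to its minimal
diagnostic statistic: four windows of `flank + repeat + flank` bases.
The two MC windows are literal substrings of the master circle; the two
AC windows are chimeras joining copy 1's flank on one side to copy 2's
(orientation-adjusted) flank on the other and occur only in the AC.  The
default flank of 300 bp anchors a ~5%-error long read uniquely while
still fitting between moderately spaced copies; the flank must be at
least 50 bp and `flank + repeat` must fit inside the smallest
recombination-product circle.

## Read classification and frequency estimation

`filter_long_reads()` applies the conventional ONT pre-filter: length
≥ 500 bp and arithmetic mean Phred quality ≥ 7, both bounds inclusive.

`classify_reads()` labels each read against the four windows of one
repeat, on both strands.  A read is *informative* only if some window
aligns end-to-end inside the read — i.e. the read spans the repeat copy
and both flank anchors — at identity ≥ `min_identity` (default 0.75, a
generous margin below what ~5% sequencing error does to a ≥ 95%-identity
window).  Exact containment is tested first with a single multi-pattern
search; reads that fail it are pre-screened for both edge 13-mers of some
window before the expensive step, then anchored by shared 13-mers and
aligned with a banded affine Needleman–Wunsch variant (pattern-global,
subject-local; match +1, mismatch −1, gap open −2, gap extend −1) written
in C++.  The read is labelled by the higher-scoring side; ties and
unalignable reads stay uninformative.  Reads are classified at every
repeat independently — a read that supports the AC at one repeat still
counts at others.

The edge-k-mer pre-screen trades sensitivity for speed on noisy reads
(an informative read is only aligned when both its window-edge 13-mers
survived sequencing error).  This loss is symmetric between MC and AC
reads — the junction geometry of the two conformations is identical — so
it thins the informative set without biasing the frequency.

`estimate_frequency()` returns $\hat f$ with a 95% interval:
Clopper–Pearson when fewer than 30 informative reads, otherwise a normal
approximation with continuity correction.  Zero informative reads give a
flagged undefined estimate, not an error.
`correlate_length_frequency()` reports Pearson's r and Spearman's ρ
between repeat length and frequency (at least three defined estimates
required), with no significance claims beyond reporting n.

`find_master_tiling()` asks the converse question — how few
MC-consistent reads cover the whole circle — by placing reads with exact
k-mer probes (a placement must cover ≥ 90% of the read) and solving the
minimal circular interval cover exactly (greedy sweep from every
candidate start interval, which is optimal for this problem); uncovered
intervals are reported when no cover exists.

## The synthetic-data generator

`generate_genome()` builds a random backbone at the requested GC
(default 45%, typical for plant mitogenomes) and plants non-overlapping
features with recorded coordinates: repeat pairs (copy 2
substitution-mutated to the requested identity, reverse-complemented for
inverted pairs), plastid-derived inserts and ORF-structured genes.  Two
details make the truth annotation exact rather than approximate: planted
copies keep their first and last bases unmutated, and the bases just
outside each second copy are forced to mismatch their diagonal
counterparts, so the planted coordinates are the true maximal extent of
the homology.  Placement keeps 30 bp of clearance between features and
repeat copies at least twice their length apart.

`simulate_long_reads()` draws reads from a mixture of circles: the MC
and, per repeat id in `ac_fractions`, its AC (for direct repeats the two
subgenomic circles are sampled proportionally to length).  Read lengths
are lognormal with `sdlog = length_sd` and
`meanlog = log(length_mean) − sdlog²/2`, so the *arithmetic* mean equals
`length_mean` while keeping ONT's heavy tail; reads longer than their
circle wrap.  Start positions are uniform, strands random, and per-base
substitution/insertion/deletion errors default to 0.05/0.025/0.025 —
ONT-like round numbers, asserted rather than fitted, and freely
configurable.  Each read's source circle, start and strand are recorded
(and survive FASTQ round trips as header tokens).  Quality strings carry
one quality value per read, drawn from N(`q_mean`, `q_sd`); the
simulator's purpose is structural truth, not a base-caller error model.

`simulate_short_reads()` emits error-free pairs at uniform coverage;
the pair count is `depth · L / (2 · read_len)`, which is what makes the
realised mean depth match the request.

`generate_genome_family()` evolves one ancestor down a star phylogeny by
per-taxon segment gains, segment losses, whole-gene deletions and
inversions (Poisson event counts).  Event breakpoints across *all* taxa
partition the ancestor into segments; the truth lists every segment's
per-taxon presence, its exact placement (and strand) in every genome,
and the resulting gene presence matrix.  Losses and gains avoid genes
entirely and inversions may contain genes but never cut them, so the
gene-level truth stays clean.  Within-taxon events never overlap;
between taxa they may.

What the generator does *not* emulate — realistic base-caller error
profiles, chimeric reads, heteroplasmy gradients, nuclear insertions of
mitochondrial DNA, substitution divergence between family members —
bounds what green tests mean: they validate the algorithms against
structural ground truth, not performance on any particular real run.

## Pan-genome layer

`read_blocks()` ingests Mugsy-style MAF (minus-strand rows are converted
to forward coordinates); `find_collinear_blocks()` is an intentionally
simple internal substitute for synthetic data: k-mers unique within each
genome are anchors, runs of anchors with an identical genome-membership
signature and collinear positions (strand flips allowed per genome)
become blocks, and uncovered regions ≥ `min_block` (default 500 bp)
are emitted as genome-specific blocks.  Because anchors are consumed
once, blocks never overlap within a genome.  Substitution-divergent real
genomes would starve this finder of anchors — real analyses should
import a proper whole-genome alignment instead.

`classify_fragments()` applies the occupancy rule — core when present in
all N genomes, specific when in exactly one, variable otherwise — and
totals per-genome bases per class over interval unions.
`accumulation_curves()` samples up to `max_perms` (default 500) genome
orderings (all orderings when N! is smaller) and reports pan(k) and
core(k) as medians with quartiles; block length for curve accounting is
the mean member span, each block counted once.  Pan curves are
non-decreasing and core curves non-increasing in every ordering by
construction, and the k = N endpoints are permutation-invariant.

## Gene content

The presence call is two-step.  `search_genes()` (seed-and-extend,
k = 15, both strands) calls `present` at identity ≥ 0.7 over ≥ 50% of
the gene length and `fragmentary` below coverage;
`validate_presence_by_depth()` then arbitrates uncertain calls by
comparing mean per-base depth over the gene (reads placed by exact
matching) with the genome-wide mean: ratio ≥ 0.5 is present, ≤ 0.1
absent, between is `uncertain` for manual review.  The band is wide
because depth near gene edges is systematically thinned by about
read_len/gene_len (boundary-straddling reads fail to place on a
gene-only reference).

`find_plastid_derived()` reports gapless hits ≥ 100 bp between the
mitogenome and a plastome.  The conventional BLASTN stringency
(E ≤ 1e-50) is translated into a minimum +1/−1 alignment score via the
Karlin–Altschul relation with ungapped nucleotide parameters
(λ = 1.33, K = 0.621): `score_for_evalue()` gives ~197 for two
organelle-sized sequences — the cutoff's role is stringency, and this
keeps it explicit and configurable rather than hiding a statistics
engine.

`find_orfs()` scans all six frames circular-aware (maximal ORFs: first
ATG after the previous stop; reported length includes the stop codon);
`flag_pseudogene()` flags an in-frame stop before 90% of the reference
length.  `build_presence_matrix()` assembles per-taxon calls into a
genes × taxa matrix, refusing missing or conflicting cells.

## Genome statistics

`feature_fraction_stats()` computes per-category bases over interval
unions; the intergenic complement subtracts only the functional
categories (coding exons, rRNA, tRNA), with plastid-derived and repeat
intervals treated as overlays.  On non-overlapping tables the functional
percentages and the intergenic percentage are additive to 100 — the
package asserts this property rather than assuming it.
`count_parsimony_informative()` uses the standard convention that gaps
and ambiguity codes are not character states.
`concatenate_supermatrix()` pads missing taxa with gaps and emits an
exactly-tiling partition table, with FASTA, relaxed PHYLIP and
RAxML-style partition writers.  Alignment trimming is accepted as input,
not reimplemented.

## The recovery study

`run_frequency_recovery()` is the package's calibration experiment: a
6 kb circle with one 300 bp inverted repeat (identity 1, copies 3 kb
apart), flank 150 bp, error-free reads with lognormal lengths around
2.5 kb, and enough reads per replicate (computed from the junction
geometry) for about 5,000 informative ones.  Across true AC fractions
0.005–0.044 and 100 replicates per fraction the estimator's absolute
bias stays well under 0.003 and 95%-interval coverage at or above 90%.
These problem sizes keep the full study to a few minutes on one core
while leaving Monte-Carlo error an order of magnitude below the bias
bound.  Error-free reads are a deliberate isolation: classification
accuracy under error is validated separately (noiseless classification
is exact; at 5% error, conditional accuracy of informative reads
exceeds 99%), so the study measures the estimator, not the aligner.

## Worked example

```{r example, eval = FALSE}
g <- generate_genome(genome_spec(
  length = 60000, gc = 0.45,
  repeats = data.frame(length = c(681, 300),
                       orientation = c("inverted", "direct"),
                       identity = c(1, 1)),
  seed = 1))
rp <- find_repeats(g)
J <- extract_junctions(g, rp[1, ], flank = 300)
reads <- simulate_long_reads(g, rp, read_sim_params(
  n_reads = 20000, length_mean = 8000, sub_rate = 0, ins_rate = 0,
  del_rate = 0, ac_fractions = c(r1 = 0.044), seed = 2))
estimate_frequency(classify_reads(reads, J))
```

## Known limitations

* Compound conformations from simultaneous recombination at two or more
  repeats are out of scope; each repeat is analysed independently, and a
  read overlapping junctions of two different repeats is classified
  independently at each.
* The internal block finder requires exact shared k-mers and is meant
  for synthetic/validation data; it is not a replacement for a
  rearrangement-aware whole-genome aligner.
* Repeat copies are planted and detected as gapless (substitution-only)
  homologies; indel-containing repeats would be split at the indel.
* The E-value translation is a stringency equivalent, not a p-value; no
  extreme-value statistics are computed.
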