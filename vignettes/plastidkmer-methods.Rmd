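---
title: "Methods: kmer detection, alignment-free distances and the synthetic study design"
author: "plastidkmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kmer detection, alignment-free distances and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the defaults it ships, and the places where a design decision was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Kmer counting

A kmer is a length-`k` window over the alphabet {A, C, G, T}. Windows
containing any other character (N, IUPAC codes) are skipped whole — the
simplest rule that is exactly testable against a sliding-window oracle.
With canonical counting each kmer is replaced by the lexicographic
minimum of itself and its reverse complement before tallying; this makes
counts strand-agnostic, which is the right frame for shotgun reads of
unknown orientation. Circular counting appends the `k − 1` wrap-around
windows, equivalent to linear extraction of `seq + seq[1:(k-1)]`; a
plastome is a circular molecule, so database construction defaults to
circular. Kmers are held 2-bit-packed in compiled code; `k` is capped at
31, which the identification default uses fully.

Two `k` regimes serve two purposes:

* `k = 31` (identification): the kmer space `4^31 ≈ 4.6e18` is so much
  larger than any genome that a random 31-mer effectively never collides
  with a reference database; matches are near-certain evidence of shared
  ancestry of the window.
* `k = 8` (phylogeny): with `4^8 = 65,536` words and ~150,000 windows per
  plastome, every genome populates most of the word space and the count
  vectors become a dense, information-rich signature suitable for
  distance estimation across whole orders of plants.

## Reference databases and detection

A database stores, per labeled genome, its set of *distinct* kmers
(presence, not multiplicity), plus the genome→taxon mapping. Presence
sets are sufficient for identification — a read either shares a window
with a reference or it does not — and make take-one-out derivation a pure
subset operation. `take_one_out(db, g)` removes one accession so that the
reads that produced an assembly are never scored against that assembly.

Per read, every kmer is looked up in the merged index; the read is
assigned to the genome matching the most kmers, provided that fraction
reaches `min_fraction` (default 0.5). Ties break by lexicographic
`genome_id`, making assignment order-independent and deterministic.
Counts are then pooled per taxon, so several accessions of one species
reinforce rather than split the signal: a kmer occurrence matching any
accession of a taxon counts once for that taxon.

A taxon is **detected** when `assigned_reads >= min_reads` (default 10)
and `unique_matched_kmers >= min_unique_kmers` (default 100), and
additionally **supported** when the binomial tail probability of its
total matched-kmer count is below `alpha` (default 1e-6) under the
chance-match null: each of the `n` queried kmers hits a taxon with `s`
distinct kmers independently with probability `p0 = s / 4^k`. At `k = 31`
this `p0` is of order 1e-13, so the support test mainly guards against
calling a taxon on a handful of stray matches; the count thresholds carry
the practical burden of separating signal from noise. A taxon passing the
count thresholds but not the support test is reported "detected, poorly
supported". The thresholds mirror the operating point of kmer
identification services whose internal criteria are not published; all
three are exposed as arguments and on the command line.

## The dilution series and the limit of detection

`dilution_series()` realizes, for each spike fraction and replicate, a
mixture of `total_reads` reads: the spike contributes
`round(total_reads * fraction / 100)` reads and the background components
fill the remainder in their stated ratios (largest-remainder rounding, so
every component is within one read of its exact share). The limit of
detection is the smallest fraction at which the target is detected with
support in *every* replicate.

The bundled design follows the study conditions this package emulates:
three plant backgrounds at 30% each, three bacterial "contaminant"
backgrounds at 3.3% each (the printed proportions sum to 99.9; they are
treated as ratios and renormalized), a spike series of 5, 2.5, 1.25, 0.6,
0.3, 0.15, 0.07, 0.03, 0.01%, three seeded replicates, and a mixture
depth of 220,000 reads — one tenth of the 2.2 million reads of the
original experiment, chosen so the full series runs in minutes on one
CPU. Replicate `r` uses seed `seed + r − 1`.

What passing this evaluation shows — and what it does not: the synthetic
spike reads are genuine plastome reads at 0.2% error against conspecific
references, and the synthetic backgrounds are unrelated random genomes.
Real whole-genome skim data is harsher: most target-organism reads are
nuclear rather than plastid, backgrounds share organellar sequence with
the database's relatives, and library artifacts exist. The measured LOD
on the synthetic twin is therefore a floor for the method's bookkeeping
(counts, pooling, thresholds, support statistics), not a claim about any
particular instrument or sample type — detection in the clean emulation
persists to smaller fractions than it would in practice.

## Take-one-out identification

Three conspecific accessions yield three databases, each omitting one;
the omitted accession's reads (10,000 per trial, 125 bp, 0.2%
substitution error) are classified against the corresponding database. A
trial is correct when the true taxon ranks first (by total matched kmers)
among detected taxa. With pairwise divergence ≤ 0.1% between accessions,
a 125 bp read keeps on average about `95 × (1 − 0.003)^31 ≈ 86` of its 95
31-mers intact against a conspecific reference, while a congener at ~2%
divergence retains roughly half of the per-kmer match probability
(`0.978^31 ≈ 0.5`) — enough to register kmer matches, far too few to win
reads. This separation is what makes the 100% assignment accuracy
reproducible.

## D2 and D2* distances

The package implements the standard inner-product D2 and the
composition-centered D2*; the original tooling around these statistics
does not publish its exact normalization, so the conventions here are
documented prominently and used consistently:

* `D2(X, Y) = Σ_w X_w Y_w`, similarity `s = D2 / sqrt(D2(X,X) D2(Y,Y))`
  (a cosine, in [0, 1]), dissimilarity `d = 0.5 (1 − s)` in [0, 0.5].
* `D2*` centers counts under a zeroth-order background model estimated
  from each sequence's own base composition: with `m` total kmers and
  `p_w` the product of base frequencies over the word,
  `D2* = Σ_w (X_w − m_X p_w)(Y_w − m_Y p'_w) / sqrt(m_X p_w m_Y p'_w)`,
  summed over the *entire* `4^k` word space. Words observed in neither
  sequence contribute `sqrt(m_X p_w m_Y p'_w)`; under the independence
  model that remainder has the closed form
  `sqrt(m_X m_Y) (Σ_b sqrt(p_X(b) p_Y(b)))^k`, so the sparse
  implementation is exact (verified against dense enumeration at `k = 3`
  to 1e-12) while touching only observed words. Normalization mirrors
  D2; since the centered statistic can be negative, the D2* dissimilarity
  lives in [0, 1] with 0.5 the expectation for unrelated sequences.
  Higher-order Markov backgrounds are out of scope.

A note on asymptotics: the self-normalized D2* of two independent
sequences does not converge to exactly 0.5 as length grows; its
fluctuation around 0.5 is governed by the word-space size (order
`4^(−k/2)`), not by sequence length. The test suite asserts what is true
— the distance stays within 0.05 of 0.5 across three orders of magnitude
of length at `k = 5`, and drops far below 0.5 for related sequences.

Assembled genomes have a defined strand, so the phylogeny pipeline
defaults to stranded (non-canonical) counting at `k = 8`; canonical
counting is available and gives a strand-agnostic variant of the
distance. Both are supported because the convention of the original
distance tooling is unstated.

## Neighbor joining, rooting, monophyly

`nj_tree()` is the Saitou–Nei algorithm with the standard Q-criterion.
Two details are pinned down where common implementations differ:

* **Tie-break**: among pairs minimizing Q, the smallest label-sorted pair
  is joined (internal nodes inherit the smallest leaf label they
  contain). Degenerate matrices therefore resolve deterministically and
  input order cannot change the result.
* **Negative branches**: a negative branch length from the standard
  formula is clamped to zero and the deficit moved to the sibling branch,
  preserving the joined pair's path length (the usual practice for
  distance trees).

On additive matrices NJ is exact; the suite verifies recovery of random
4- and 5-taxon additive trees to machine precision and agreement with an
independent implementation (`ape::nj`) on noisy matrices. Rooting places
the root at the midpoint of the outgroup's pendant edge; monophyly of a
label set means the smallest containing clade holds no other tips.
PHYLIP square matrices are written with labels padded to 10 characters
(longer labels kept intact, "relaxed" style) for interoperability with
classic tree software.

## Variant screen

`call_variants()` consumes an existing whole-genome alignment (built
upstream, e.g. with MAFFT) and scans columns once per query. Coordinates
are 1-based inclusive on the reference's ungapped sequence, matching the
convention in which a 17 bp deletion printed as 58,399–58,415 satisfies
`end − start + 1 = 17`. Maximal gap runs become single indel calls;
insertions anchor at the preceding reference position (0 at the alignment
start); adjacent SNPs and indels are reported separately (no
complex-variant merging — the simplest verifiable convention); `N` is
missing data and produces no call, and a run of N columns breaks an indel
run. Columns gapped in both sequences of a pair belong to other rows of
the alignment and are dropped before pairwise comparison. Where source
material prints a deletion with descending coordinates, this package
always emits ascending ones.

## The synthetic-data generator

The generator exists so that every stage is testable offline, and its
defaults *are* the study conditions the package evaluates:

* **Genomes**: i.i.d. bases at GC 0.37 (typical plastome composition),
  length 150,000 for panels (plastome scale; the genomes this design
  emulates are ~158.8–158.9 kb). i.i.d. sequence has no inverted repeat,
  no gene structure and no repeat families — fine for exact-matching and
  distance arithmetic, silent on repeat-induced ambiguity.
* **Panels**: one ancestor; conspecific accessions mutated at 5e-4 each
  (pairwise ~0.1%), congeners at 2%, confamilials at 10%, an outgroup at
  25% — a nested divergence ladder whose recovery the phylogeny tests
  assert. Panel mutation is substitution-only so all panel genomes stay
  positionally alignable by construction.
* **Reads**: fixed 125 bp (the read length of the emulated experiment),
  uniform circular start positions, random strand, i.i.d. substitution
  errors at 0.2%, constant quality 'F' (Q37) so simulated reads pass the
  default quality filter; the filter is still applied in the evaluation
  pipelines to exercise the module.
* **Mixtures**: label provenance is kept in read ids (`label|id`),
  shuffling is seed-deterministic, and pools are sampled without
  replacement unless explicitly allowed. The same design with the same
  seed is byte-reproducible.

One documented RNG convention: every operation takes a `seed` and
restores the caller's RNG state, so library calls never perturb a
session's randomness.

## Quality filter

A read passes when its length is at least 100 bp and the median of its
Phred scores is at least 25, both inclusive; the median of an even-length
list is the mean of the two central order statistics. Reads without
qualities (FASTA) face the length rule only. Phred encoding is offset-33
(Sanger/Illumina 1.8+), configurable. Whole reads are filtered — no
quality trimming or truncation is performed, since the upstream
experiment's trimming happened before its filter and the interaction is
unspecified. N bases pass through; the kmer layer skips them. The filter
is idempotent and order-preserving.

## Problem sizes and runtime

The shipped evaluations use: 150 kb genomes; 10,000 reads per
take-one-out trial (three trials); 220,000-read mixtures over the 9-point
spike series with 3 replicates; `k = 31` databases over 9 genomes; D2 at
`k = 8` over the 9-genome panel. On one CPU the full test suite runs in
roughly three minutes and `scripts/acceptance.R` in roughly two and a
half; these sizes were chosen as the smallest at which the three
qualitative regimes (conspecific, congeneric, unrelated) are cleanly
separated by the statistics above.

## Known limitations

* Detection is presence/absence at the taxon level: no abundance
  estimation, no lowest-common-ancestor logic for reads matching several
  taxa equally, no paired-end awareness.
* `k` is limited to 31 by the 2-bit packing; databases with more than a
  few dozen plastome-scale genomes are held in memory uncompressed.
* The D2/D2* normalizations are this package's documented conventions;
  numerical values are not interchangeable with other tools' output,
  though tree topologies on well-separated data should agree.
* The variant screen trusts the supplied alignment; alignment errors
  (especially around repeats) propagate directly into calls.
* Synthetic backgrounds are unrelated random genomes; real mixtures
  contain relatives of database entries and shared organellar sequence,
  so real-data detection limits will be less favorable than the
  synthetic twin's.
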