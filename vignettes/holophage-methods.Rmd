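---
title: "Methods: integrative phage-host prediction and lifestyle analysis"
author: "holophage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative phage-host prediction and lifestyle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Phages in a host-associated microbiome (a holobiont such as a marine
sponge) leave three kinds of computational fingerprints in the genomes of
the bacteria they infect: spacers in CRISPR arrays (a record of past
infection), integrated prophage segments (a record of lysogeny), and
shared tRNA genes (phages often carry host-derived tRNAs). `holophage`
implements all three evidence channels over assembled contigs, combines
them into a bipartite infection network, and asks two ecological
questions: do phages enriched in one environment preferentially infect
bacteria of the matching niche (stratification), and is the temperate
(lysogenic) replication mode more prevalent or abundant than the lytic
one in a given environment?

Because real communities come without ground truth, the package ships a
synthetic holobiont generator that plants every signal with known
coordinates, so each stage is testable end to end and its failure modes
are measurable.

## Evidence channels and their acceptance rules

**CRISPR channel.** Arrays are detected with a deliberately simple,
deterministic repeat-spacer detector: exact 13-mers occurring at least 3
times with consecutive spacings inside the feasible repeat-plus-spacer
period window (38-108 bp) seed a candidate; seeds sharing a span are
grouped, the repeat unit is the union of their relative offsets, and
candidates are validated against repeat length 21-48 bp, spacer length
17-60 bp, and mean repeat identity to the column-majority consensus of at
least 0.9. Boundary columns with imperfect cross-copy agreement are
trimmed, so mutation-free arrays are recovered at exact coordinates. One
identifiability caveat: when the base adjacent to every repeat copy
coincides by chance, that column is indistinguishable from repeat and the
detected boundary extends one base past the planted one; the tests
tolerate exactly this case.

Spacers are matched to phage contigs ungapped over their full length on
both strands, accepting at most 1 mismatch. The stringent
one-mismatch-over-full-length rule makes gapped alignment irrelevant,
which is why the matcher is a Hamming scan (implemented via
`Biostrings::matchPattern`) and is verified in the tests against a naive
sliding-scan oracle. Ties among hits of one spacer are broken by fewest
mismatches, then leftmost phage position, then + strand. Each linked
(phage, host) pair contributes one evidence link regardless of how many
spacers hit.

**Homology (prophage) channel.** Phage-host local alignment uses
Smith-Waterman scoring with match +1, mismatch -1, and affine gaps
costing 10 + 10 per base — gaps are therefore rare and alignments nearly
ungapped. Small problems (up to 4e6 cells) are solved by exact dynamic
programming; larger ones are seeded with exact 11-mer matches, clustered
by diagonal band and subject-position gaps, merged where windows overlap,
and solved exactly within each window. The top score is checked against
`Biostrings::pairwiseAlignment` (an independent exact implementation) in
the tests. The E-value cutoff used with database searches is replaced by
a raw score threshold of 50 (about a 50 bp exact match): the identity and
length filters dominate acceptance, and a raw threshold is deterministic
without database-size statistics.

An alignment becomes a prophage link when identity exceeds 0.80 over a
host span of at least 1 kb and at most half the host contig length; the
best-scoring surviving alignment per (phage, host) pair is kept. For host
contigs under 2 kb this window is empty — such alignments are rejected
and a message notes how many. A noteworthy emergent effect in the
synthetic data: two independent back-translations of the same marker
protein are ~80% identical at the nucleotide level (first and second
codon positions agree), so temperate phages weakly align to prophages of
*other* temperate phages; these alignments are shorter than 1 kb and are
rejected by the span rule.

**tRNA channel.** tRNA gene prediction is an input (annotations in
GFF3); the package extracts the annotated, strand-oriented sequences and
aligns every phage tRNA to every host tRNA with an end-free (overlap)
global alignment (match +1, mismatch -1, gap -2; exact DP is cheap at
tRNA sizes, via `Biostrings::pairwiseAlignment(type = "overlap")`). A
candidate needs identity of at least 0.95 over an aligned region covering
at least 0.9 of the shorter sequence; the coverage floor is this
package's addition — an identity threshold alone would accept 10 bp
spurious overlaps — and is configurable. Per phage tRNA only the single
best hit is kept (highest identity, then coverage, then host id
lexicographically, with ties logged); whether "best hits" should be per
tRNA or per contig was open, and per-tRNA was chosen as the stricter
reading.

## The infection network and the stratification test

Links from all channels are deduplicated per (phage, host) pair with
channel evidence unioned; only nodes with at least one edge enter the
network. Phage enrichment labels come from the abundance table on a
copy-per-kilobase (Cpk) scale: a phage is sponge-enriched when its mean
Cpk in sponge samples is at least 2-fold its seawater mean and it is
detected in at least half the sponge samples (symmetrically for
seawater; phages absent everywhere are unknown, the rest mixed).

The environmental partitioning table counts, for each phage, every
distinct host niche it links to once (a phage spanning two niches
increments two cells). A per-edge counting mode is available, since the
tabulation rule admits both readings.

Stratification is tested by label randomization. The statistic is the
difference of conditional proportions over edges,

P(edge reaches a sponge-symbiont host | phage labelled sponge) −
P(edge reaches a sponge-symbiont host | phage labelled seawater),

bounded in [−1, 1], equal to 1 under complete separation and 0 in
expectation when labels are independent of niches. The source analysis
reports only a helper package and a statistic value, not the statistic's
definition, so this package defines its own transparent, enumerable
statistic and makes it pluggable; the original value is therefore not
reproducible and is not a target. Labels are permuted uniformly among
phage nodes with edges fixed, and the p value uses the add-one rule
(1 + #extreme)/(1 + n), two-sided by default on |statistic|; the minimum
attainable p is 1/(n+1). Replicates where a label class ends up with no
edges are resampled (impossible when both classes exist among matched
phages, since permutation preserves the label multiset). Tests verify
calibration (rejection rate at alpha 0.05 within the exact binomial
interval over 400 null networks at 500 permutations) and power (p <=
0.05 on all of 50 completely separated networks).

## Lifestyle calling and temperate:lytic ratios

Replication mode is called by an ensemble with marker precedence: any hit
of an ORF against an integrase/excisionase-like exemplar forces a
temperate call; otherwise a k-nearest-neighbour classifier on normalized
tetranucleotide frequencies votes, and a call stands only when the
winning vote fraction reaches 0.6 (k = 5 by default; both configurable).
Everything else is explicitly unclassified — in real virome data most
contigs get no call, and the unclassified class keeps that visible.
Marker precedence means adding a marker hit can flip a call only toward
temperate, never away. ORFs are maximal start-to-stop reading frames
(first ATG after a stop, standard code, six frames, minimum 60 aa),
verified against brute-force enumeration. Marker detection is local
protein alignment (BLOSUM62, gap open 10 / extend 1) requiring identity
>= 0.35 over >= 0.5 of the exemplar length; 100 shuffled-exemplar
controls yield zero hits in the tests.

The bundled exemplars are *synthetic stand-ins* (fixed random proteins,
`inst/extdata/markers_synthetic.faa`): the generator back-translates the
first of them into planted marker ORFs, so detection against this set
recovers planted markers at ~100% identity. They are not real enzyme
sequences; users analysing real data should supply their own exemplar
FASTA. Likewise the k-NN classifier is a transparent stand-in for a
pre-trained composition classifier: it is trained on labelled reference
sequences generated under the same composition-bias model as the
community (GC shift delta = 0.05 by default), and its held-out accuracy
at that bias level is >= 0.9 in the tests. How marker evidence should
interact with a composition classifier when they disagree was open;
marker precedence was chosen because a bona fide integrase ORF is direct
evidence of integration ability.

Temperate:lytic ratios are computed per environment as the ratio of Cpk
sums over temperate and lytic phages (unclassified excluded), plus the
contig-count ratio; a zero lytic denominator is reported as +Inf with a
flag. Cpk ratios are invariant to per-sample count scaling.

## Spot quantification

Fluorescence spots are counted as local maxima with prominence above a
tolerance t: a maximum is reported iff flooding its basin downward from
the peak to (peak − t) reaches no higher pixel. The implementation
computes the full persistence diagram once per image — pixels are
processed in decreasing intensity with a union-find; a component dies at
the level where it meets a higher-peaked one, with prominence = peak −
merge level; the global maximum gets peak − image minimum — so counts for
any threshold are a single filter over prominences. Two design points
make counts deterministic: connected equal-valued plateaus are one
maximum represented by the pixel nearest the plateau centroid, and
equal-valued peaks connected within the flood range collapse to one
(smallest-index peak survives). The latter rule is forced by
consistency: with two equal peaks and a tolerance above the saddle gap,
exactly one maximum must be reported. Reporting requires prominence
strictly greater than t, so a constant image has zero maxima for every
t >= 0. Edge pixels are eligible maxima (no border exclusion; the
borderless contract is the simplest deterministic choice). The
implementation is verified against an exhaustive per-plateau flood oracle
on random images.

The prominence threshold is chosen from control images: over a candidate
grid, pick the value maximizing mean count on positive controls minus
mean count on negatives, subject to the negative mean not exceeding 1
spot per image, ties to the larger threshold. This objective is one
concrete formalization of optimizing a signal-to-noise threshold and is
pluggable.

Group comparison uses the tie-corrected Kruskal-Wallis test (base R)
followed by Dunn's pairwise z tests on pooled ranks with
Benjamini-Hochberg adjustment across pairs, significance at adjusted
p < 0.05. Counts, not intensities, are the analysis unit.

## The synthetic generator: what it emulates and what it does not

Background sequences are i.i.d. uniform nucleotides, so false-positive
rates of all matchers are analytically predictable; there is no gene
content, codon structure, or phylogeny. Planted features overwrite
background slices (rather than inserting), keeping all coordinates
stable; placement is rejection-sampled against previously occupied
intervals with at most 100 retries. Per (phage, host) pair, each channel
links with its own Bernoulli probability, drawn under a seed derived from
the community seed so tests can replay the draws. tRNA cassettes are
planted before spacers and prophage segments are sliced, so every planted
signal refers to the final phage sequence. Spacer and tRNA fidelities use
exact substitution counts (so threshold examples are deterministic);
prophage identity uses i.i.d. per-base substitution (so mismatch counts
are binomial, as a sequence-evolution model would give).

Abundance counts are negative binomial (dispersion 0.2 by default, a
realistic virome-scale overdispersion; 0 gives Poisson) around
environment-specific means: an enriched phage has its full mean
(default 20 Cpk times contig kb) at home and mean/fold (default fold 8)
elsewhere, so an infinite fold gives structural zeros away from home.
Temperate phages get a planted marker ORF — a back-translation of the
bundled exemplar behind an in-frame stop guard, so the maximal ORF starts
exactly at the planted ATG — and a GC composition shift of delta = 0.05.
By default link placement is independent of labels (the null for the
stratification test); `assortative = TRUE` restricts links to compatible
label pairs, producing planted stratification.

Passing tests on these communities demonstrate the machinery (detection,
matching, filtering, testing) under controlled signal levels; they do not
demonstrate performance on real metagenomes, where composition bias,
repeats, and incomplete assembly violate the uniform background
assumption, and where the simplified array detector will be less
sensitive than dedicated CRISPR tools whose quality models it omits.

## Problem sizes and numerical choices

The default community is 20 phages (5-20 kb) by 10 hosts (30-60 kb) with
link probabilities 0.15/0.12/0.12, sized so the full pipeline runs in
under a minute on one CPU; the permutation test default in the analysis
scripts is 10,000 randomizations (the package-level default), while tests
use 200-1000 where only calibration matters. Test suites use 400 null
networks at 500 permutations for calibration and 200 random 12 x 12
images for the maxima oracle. All randomness flows from explicit seeds;
stage seeds are derived from the community seed by name hashing so stages
can be re-run independently (and all derived seeds stay below 2^31).

Known limitations: the array detector requires an exact 13-mer shared at
consistent period (heavily mutated repeats can evade it); the
seed-and-extend aligner demands two 11-mer seeds in a window, so
alignments shorter than ~25 bp or below ~65% identity are invisible
outside the exact-DP regime (irrelevant at the 1 kb / 80% acceptance
window); the composition classifier assumes the bias that separates
lifestyles is compositional and stationary along the contig; and the
imaging stage models isotropic Gaussian spots on flat background, not
structured autofluorescence.
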