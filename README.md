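# holophage

Integrative phage–host prediction and lifestyle analysis for holobiont
(host-associated) microbial communities, with a fully synthetic,
ground-truthed test bed.

## The problem

Which bacteria do the phages of a holobiont — a marine sponge and its
microbiome, say — actually infect, and how do they replicate there?
Assembled metagenomes leave three computational fingerprints of
phage–host relationships:

* **CRISPR spacers**: short phage-derived sequences archived between
  near-identical repeats in bacterial genomes. A spacer matching a phage
  contig over its full length with at most 1 mismatch links that phage to
  that host.
* **Integrated prophages**: lysogens carry phage genome segments. A local
  alignment with identity > 80% spanning between 1 kb and 50% of the host
  contig links phage and host.
* **Shared tRNAs**: phages often carry host-derived tRNA genes; a best
  hit at ≥ 95% identity links them.

`holophage` implements all three channels, combines them into a bipartite
**infection network**, labels each phage's environmental enrichment from a
read-count table on a copy-per-kilobase (Cpk) scale, tabulates the
partitioning of phage sources across host niches, and tests whether the
network is **stratified by environment** with a label-randomization
permutation test on the statistic

```
diffprop = P(edge hits a sponge-symbiont host | phage labelled sponge)
         - P(edge hits a sponge-symbiont host | phage labelled seawater)
```

(bounded in [-1, 1]; 0 in expectation when labels are independent of host
niches; p value by the add-one rule over label permutations).

Replication mode (**temperate vs lytic**) is called by an ensemble with
marker precedence — any ORF hit against an integrase/excisionase-like
exemplar forces a temperate call; otherwise a transparent k-NN classifier
on tetranucleotide composition votes, and low-confidence phages stay
unclassified — followed by per-environment temperate:lytic Cpk ratios and
the contig count ratio. A prominence-based maxima finder (the "noise
tolerance" style of spot detection) with control-driven threshold
selection and Kruskal–Wallis/Dunn/Benjamini–Hochberg group comparison
quantifies fluorescence spot counts per tissue region.

Because real communities come without ground truth, the package includes a
synthetic holobiont generator that plants CRISPR arrays, prophage
segments, shared tRNA genes, marker ORFs, and environment-structured
negative-binomial abundance profiles with complete, machine-readable
truth. Every stage is tested against that truth and against independent
oracles (naive Hamming scans, exact dynamic programming via Biostrings,
exhaustive flood enumeration, brute-force tallies).

## Worked example

```r
library(holophage)
report <- run_pipeline(community_config(seed = 3), n_perm = 500)
print(report)
```

```
Pipeline report (seed 3 )
  links: crispr=27 homology=30 trna=21 (pairs=69)
  channel n_pred n_truth tp precision recall
   crispr     27      27 27         1      1
 homology     30      30 30         1      1
     trna     21      21 21         1      1
  enrichment label accuracy: 1.000
  stratification: observed=-0.0962 p=0.4691 (n_perm=500)
  lifestyle: lytic=8 temperate=12; marker sensitivity 1.000
  temperate:lytic count ratio: 1.500 (12/8)
```

Reading this: the generator planted 27 CRISPR, 30 prophage, and 21 tRNA
links in a 20-phage x 10-host community; each channel recovered exactly
its planted links (precision = recall = 1 at the default mutation-free
settings). All 20 enrichment labels were recovered from the simulated
abundance table. The default community places links independently of
labels — a true null — and the permutation test correctly declines to
reject (p = 0.47). All 12 temperate phages were called temperate via their
planted integrase-like marker ORFs, the 8 lytic ones via the composition
classifier, giving a contig count ratio of 12/8 = 1.5.

The numbered scripts under `analysis/` run the same workflow step by step
(simulate → predict hosts per channel → network + stratification test →
lifestyle ratios → spot quantification), each printing what it found and
writing tables under `results/`:

```sh
Rscript analysis/01_simulate_community.R
Rscript analysis/02_predict_hosts.R
Rscript analysis/03_network_stratification.R
Rscript analysis/04_lifestyle_ratios.R
Rscript analysis/05_spot_quantification.R
```

See `vignettes/holophage-methods.Rmd` for the model, every threshold and
default with its rationale, and known limitations.

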