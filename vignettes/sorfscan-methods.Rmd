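---
title: "Conserved small-ORF discovery with sorfscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved small-ORF discovery with sorfscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorfscan)
library(dplyr)
```

## The problem

Standard gene callers routinely skip open reading frames shorter than
about 80-100 codons, because short random DNA produces abundant spurious
ATG-to-stop intervals and length filters are the cheapest guard against
them. Yet many genomes encode functional peptides in exactly this size
range (ribosomally translated small ORFs, "sORFs"), often sitting in
regions annotated as intergenic or intronic. A practical way to separate
real sORFs from noise without expression data is comparative: a short ORF
that is independently present, with recognisable sequence identity, in
two or more related genomes is much more likely to be functional than one
found once.

`sorfscan` implements that comparative workflow end to end for a set of
annotated genomes (FASTA + GFF3 per species):

1. partition each genome into exonic, intronic and intergenic space;
2. harvest *annotation-derived* sORFs: transcripts whose CDS encodes at
   most 80 residues;
3. scan both strands of the intergenic and intronic sequence for ORFs
   with both a start and a stop codon and at most 80 codons
   (240 nt), using two predictors — a plain six-frame scanner and a
   hexamer coding-potential classifier thresholded at probability 0.5 —
   and keep their consensus;
4. pool both sources, screen the peptides against all annotated proteins
   by local alignment (hits below two-thirds query coverage and below 30%
   identity are discarded), and remove 100%-identical duplicates within
   each genome;
5. cluster the pooled peptides greedily at 70% identity and call a
   cluster *conserved* when its members span at least two species;
6. for each conserved cluster, estimate pairwise JTT distances, build a
   neighbor-joining tree, and attach bootstrap supports.

Every stage is exposed as a function over tibbles, so intermediate
results can be inspected, filtered or re-entered with ordinary dplyr
verbs.

## Region partition

GFF coordinates are converted to 0-based half-open intervals at the I/O
boundary; all internal arithmetic uses that convention. Exonic intervals
are the reduced union of exon features (CDS is the fallback when a GFF
carries no exons). Gene spans come from gene features, falling back to
mRNA, then CDS. Intronic intervals are the intragenic complement of the
exonic union; intergenic the complement of everything else. The three
label sets tile each sequence exactly — asserted by a test — with the
precedence exonic > intronic > intergenic at annotation conflicts, so no
candidate space is double-counted and nothing inside a known CDS is
re-predicted under an "intergenic" label. Intergenic regions are not
trimmed near gene boundaries; no UTR buffer is applied.

## ORF scanning

`scan_orfs()` examines the three frames of a supplied strand; the caller
(or `scan_bundle()`) provides the reverse complement for the other
strand and mirrors the coordinates back. Only `ATG` is accepted as a
start codon. A codon containing `N` is neither start nor stop and breaks
the open frame, so no reported ORF spans ambiguous sequence. The default
`longest_per_stop` mode reports the most-5' ATG per (frame, stop) pair,
matching the one-gene-per-stop behaviour of classical ORF callers;
`all_starts` is available for sensitivity analyses. `n_codons` counts
amino acids excluding the stop, and the 240-nt cap is interpreted as
`n_codons <= 80`. The default floor is `min_codons = 10`: conserved
sORFs as short as 11 residues are reported in the literature, and 10
keeps them recoverable while damping the flood of very short random
ORFs. The scanner is checked exactly against a brute-force enumerator on
random sequences.

Kozak context is reported per candidate: `positive` requires a purine at
position −3 of the ATG and `G` at +4, strand-aware; candidates whose
context leaves the sequence (or touches `N`) are `undetermined`. This
motif rule is a deliberate, documented stand-in for ORF-integrity-based
calls of coding-potential web tools, and is labelled as such in output.

## The hexamer coding-potential model

The second predictor is a trainable hexamer log-odds classifier,
standing in for dedicated sORF-finding tools whose internal model is not
otherwise reproducible. Training counts overlapping 6-mers (step 1,
`N`-containing windows skipped) in a coding corpus and a noncoding
corpus and forms

\[ \mathrm{lo}(h) = \log \frac{P(h \mid \text{coding})}{P(h \mid \text{noncoding})} \]

with an additive pseudocount (default 1) guaranteeing finite values. A
sequence scores the mean log-odds over its windows, mapped to a
probability by a logistic calibration \(p = \mathrm{logistic}(a s + b)\).
Candidates with \(p \ge 0.5\) (boundary inclusive, applied per ORF) and
at most 80 codons pass the filter.

Two calibration details matter and were chosen deliberately:

* **Held-out fitting.** The log-odds table memorises rare hexamers of
  its own training sequences, so scores of in-corpus sequences are
  inflated. Calibration therefore uses a split: a half-corpus model
  scores the other halves, and the final table is rebuilt on the full
  corpora with the calibration kept.
* **Moment (discriminant) solution on fixed windows.** Held-out
  sequences are chopped into 240-nt windows (the length scale of the
  ORFs being judged) and the classes balanced. Because well-trained
  corpora separate completely, a maximum-likelihood logistic fit has no
  finite optimum and its boundary floats anywhere inside the class gap;
  we instead use the closed-form equal-variance-Gaussian solution
  \(a = (\mu_1-\mu_0)/s^2\), \(b = -a(\mu_1+\mu_0)/2\), which is the
  population logistic, is always defined, and pins \(p = 0.5\) at the
  class-mean midpoint. Degenerate cases (identical corpora, constant
  scores) fall back to \(a = 1, b = 0\), so every sequence scores 0.5
  under a null model.

In `run_pipeline()` the model is trained once on the pooled corpora of
all input species — spliced CDS as coding, forward-strand intergenic
sequence as noncoding. Pooling is preferred over per-species training
because the species of a comparative study share codon usage at the
resolution a hexamer table can express, and the tripled corpus measurably
stabilises both the table and the calibration boundary. Sequences shorter
than 6 nt (or with no `N`-free window) cannot be scored and are reported
as probability 0.5 with a `too_short` flag. The 0.5 threshold is applied per ORF, not per region.

## Consensus and pooling

The scanner set and the coding-filtered set are intersected. The default
`exact_interval` mode requires identical (sequence, strand, start, end)
keys — the strictest reading of "overlapped" and fully reproducible. A
`shared_stop` mode keys on the stop-codon coordinate only and keeps the
scanner's coordinates, accommodating predictors that pick different ATGs
for one gene; both interpretations are implemented because "overlapped"
admits either reading. Pooling with the
annotation-derived records collapses duplicate intervals with annotation
winning, mirroring the use of existing annotation as the reference set.
Record identifiers follow the `gi`/`sf` convention for
annotation-derived versus ab-initio records.

## Homology screen

Candidates are already peptides, so a protein-protein Smith-Waterman
search (BLOSUM62, gap open 11, extend 1) against all annotated proteins
replaces a six-frame translated search with no loss for this pipeline;
scores are verified integer-exact against a brute-force dynamic-programming
oracle. Identity counts identical columns over all alignment columns
(gaps in the denominator); coverage is the aligned fraction of the
query. The published removal rule — hits aligning to less than two
thirds of the query *and* with less than 30% identity are removed — is
grammatically ambiguous; the default `AND_retain` keeps only hits
passing both thresholds (the strict reading, minimising false homology),
while `OR_retain` implements the literal "removed only if both fail"
reading. Both are exposed and logged. The best retained hit per query
(ties toward `known_function`) sets the record's homology status; no
E-value statistics are computed, as filtering is purely
coverage/identity.

## Deduplication and clustering

Exact duplicates (nucleotide sequence when available, else peptide) are
removed *within each genome* — cross-species identical sequences are
independent observations and must survive, or conservation itself would
be erased. Clustering is greedy and longest-first in the style of CD-HIT:
records sorted by decreasing peptide length (ties by identifier) either
join the first existing cluster whose representative they match at ≥70%
identity, or found a new cluster. Identity is identical columns of the
optimal global alignment divided by the shorter sequence's length —
CD-HIT's convention; the alignment type (global) is our choice, as the
sources do not state one. The canonical sort makes clustering
order-invariant, and the member-to-representative identity bound is
re-checked post hoc in tests.

An exact dimer-count screen prunes representative comparisons that
provably cannot reach the threshold (an alignment with \(t \cdot m\)
identical columns shares at least \(2tm - n - 1\) dimers, for shorter
length \(m\) and longer \(n\)); the screen only skips alignments whose
identity must fall below threshold, so output is identical with it on or
off — also asserted by a test.

A cluster is conserved when its members span ≥2 species; singleton and
single-species clusters are not. Conservation breadth (fraction of
surveyed genomes covered) is reported per conserved cluster in quarter
bins. Chance agglomerations of very short background ORFs do occur at
70%/shorter-length identity — a 10-mer needs only 7 matching columns
against a longer representative — so conserved clusters with no planted
(or otherwise corroborated) content are expected in noisy candidate
space and are reported separately by `score_recovery()`.

## Distances, trees, bootstrap

For each conserved cluster with at least three members, members are
stacked onto the representative by global alignment (insertions relative
to the representative dropped, deletions gapped) — a
representative-anchored pseudo-alignment that avoids an external
multiple-alignment dependency; an externally computed MSA of equal-length
rows can be substituted anywhere an alignment is accepted.

Pairwise distances are maximum-likelihood estimates under the
Jones-Taylor-Thornton amino-acid model: the published exchangeabilities
and frequencies are embedded, the rate matrix is normalised to one
expected substitution per site and eigen-decomposed once, and
\(\hat d = \arg\max_t \sum_i \log[\pi(a_i) P_{a_i b_i}(t)]\) is found by
bounded 1-D search on \([0, d_{\max}]\) with \(d_{\max} = 5\) as the
saturation cap. Columns containing a gap or `X` are excluded per pair
(complete pair-wise exclusion). Pairs with fewer than 10
comparable columns are flagged unreliable but still returned. The
estimator is validated against simulation (coverage at \(t = 0.3\)) and
against an independent implementation.

Trees are built by Saitou-Nei neighbor joining, implemented directly so
its contract is explicit: the Q-criterion minimiser is joined at each
step with ties broken toward the smallest index pair, negative branch
lengths are clamped to zero with the deficit moved to the sibling edge,
and the output is an unrooted `phylo` with a basal trifurcation. NJ
recovers the generating tree exactly on additive matrices (tested to
1e-9) and agrees topologically with an independent implementation.
Bootstrap resamples alignment columns with replacement, rebuilds
distances and tree per replicate, and reports the fraction of replicates
containing each internal bipartition; runs are bit-identical given the
seed. Outgroup rooting is a display-time option, not part of inference.
Newick output writes branch lengths with six decimals and quotes labels
containing metacharacters.

## The synthetic fixture generator

`generate_genomes()` builds, per species: i.i.d. background DNA at a
configurable GC content; multi-exon ordinary genes (>80 codons) whose
proteins are reverse-translated with a biased codon table (preferred
codon weighted 6:1 within each synonymous family) so that coding
sequence carries a hexamer signature the classifier can learn; a few
annotated single-exon sORF genes; and homologous sORF families planted
into intergenic or intronic space. Family copies are mutated from a
common ancestor with codon-aware substitutions biased 2:1 toward
synonymous changes, so peptide identity decays more slowly than
nucleotide identity, as in real conservation; at the default rate 0.05
within-family peptide identity stays comfortably above the 70%
clustering threshold. Each copy is planted behind an adjacent in-frame
stop codon, guaranteeing that its ATG is the most-5' start for its stop
and that a longest-per-stop scan recovers the exact planted interval.
Planted intervals never overlap each other or genes; generation is fully
deterministic given the seed.

What the generator does *not* emulate: indels within planted sORFs
(substitutions only), repeat content, GC heterogeneity, alternative
splicing, overlapping genes, and real codon-usage tables. Passing the
end-to-end recovery test therefore demonstrates that the machinery is
correct and calibrated under these idealised conditions — not that the
same recall would be achieved on real fungal genomes, where weaker codon
bias, repeats and annotation errors all cut into it.

The default study conditions (the "smoke" fixture) are 3 species of
200 kb, 40 ordinary genes and 2 annotated sORFs per species, 10 planted
families of 11-80 codons in 2-3 species each at substitution rate 0.05,
70%/30% intergenic/intronic placement. `score_recovery()` matches
cluster members to planted copies by exact interval; a family is
recovered when one conserved cluster holds its copies from ≥2 species
and no other family's (purity). Impure clusters (mixing families) are
counted as `false_cluster_count`; conserved clusters matching no truth
at all — the chance short-peptide agglomerations described above — are
reported separately and are expected to be nonzero even in a negative
control.

## Numerical and reproducibility choices

* All thresholds are boundary-inclusive (probability ≥ 0.5, identity
  ≥ 0.70, coverage ≥ 2/3, identity ≥ 0.30) — fixed for determinism.
* All randomness (generator, bootstrap) flows from explicit seeds; the
  pipeline derives per-cluster bootstrap seeds as `seed + cluster index`.
  Reruns with identical config and seed are byte-identical, including
  TSV and Newick artifacts.
* Problem sizes in the shipped tests: the scanner oracle runs 200
  sequences up to 2 kb; the alignment oracle 100 peptide pairs up to
  50 aa; classifier validation 500 + 500 training and test sequences per
  class; JTT recovery 100 replicates of 500 sites; end-to-end recovery
  three smoke-fixture seeds plus a zero-family negative control. These
  sizes give stable pass/fail behaviour for the stated tolerances while
  keeping a full test run inside a normal desk-scale budget.

## Known limitations

* Candidates are single-exon by construction; no splice-aware ORF
  assembly across introns.
* Only `ATG` starts are considered.
* The hexamer classifier's resolving power on ORF-length fragments is
  modest; a short coding sequence whose composition happens to look
  background-like will be lost at the 0.5 threshold, which is why the
  consensus design deliberately errs toward precision over recall.
* The homology screen has no E-value model; coverage/identity filtering
  only.
* Greedy first-fit clustering reproduces the cited tool's semantics but
  is not a globally optimal partition.

## A minimal session

```{r example, eval = FALSE}
spec <- plant_spec(seed = 1)
gen <- generate_genomes(spec)
run <- run_pipeline(gen, pipeline_config(seed = 101, bootstrap_reps = 100))
glance(run)
score_recovery(run$clusters, gen$truth)
plot_conservation_breadth(run$breadth)
```
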