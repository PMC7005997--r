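---
title: "Methods: comparative genomics of a small bacterial clade"
author: "cladescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of a small bacterial clade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cladescope packages the computations that recur in comparative studies of
newly sequenced bacterial genomes — here tuned to the setting of a small clade
of thermophilic cyanobacteria with one outgroup: screening for horizontally
acquired genes, species delimitation by average nucleotide identity (ANI),
pangenome phyletic accounting on a species tree, GC landscape analysis, and
exact-match synteny. Every stage can be exercised end to end on a seeded clade
simulator, so the package's claims are tested against known truth rather than
against irreproducible database snapshots. This vignette describes each model,
its assumptions, the tunable parameters, and the design decisions taken where
the methods literature leaves choices open.

## The clade simulator

`simulate_clade()` evolves one ancestral chromosome down a rooted,
branch-length-bearing tree:

* **Substitutions.** DNA evolves under Jukes–Cantor: on a branch of length
  $t$ substitutions/site, each site changes with probability
  $\tfrac{3}{4}(1 - e^{-4t/3})$, uniformly to another base. Protein families
  evolve under the analogous Poisson model ($1 - e^{-t}$, uniform over the 19
  other residues) and are indel-free, so family members stay aligned by
  construction and no multiple-alignment step is needed downstream.
* **Horizontal acquisitions.** Each branch receives a Poisson number of
  insertion events with mean `hgt_rate` × (branch length / tree height):
  opportunity proportional to time. An event inserts a contiguous new gene
  with GC drawn at `donor_gc`, placed at a uniformly chosen intergenic point,
  at the start of its branch. Events on terminal branches are labelled
  `hgt_recent`; events on internal branches are shared by all daughter leaves
  and labelled `hgt_ancestral` — mirroring how taxonomic screens read
  best-hit evidence (a transfer that predates the radiation of the genus
  leaves same-genus best hits).
* **Amelioration.** No quantitative model for compositional amelioration is
  standard; we formalize it as a linear decay of the donor–host GC offset:
  after time $t$ since insertion the residual offset is
  $(\mathrm{GC}_{donor} - \mathrm{GC}_{host}) \cdot \max(0, 1 - \alpha t)$
  with $\alpha$ = `amelioration_rate`. The target composition is the leaf's
  *realized* background GC (the native genome itself drifts slightly toward
  0.5 under the symmetric substitution model), and the adjustment resamples
  each site's GC/AT category independently. That detail matters: a fully
  ameliorated segment is then compositionally exchangeable with native
  sequence — same mean *and* same binomial variance — which is exactly the
  null hypothesis the landscape permutation test needs to be calibrated
  against.
* **Rearrangements and the mobilome.** Named lineages receive chromosomal
  inversions (boundaries at intergenic points, annotations remapped and
  strands flipped; boundaries of earlier inversions are remapped through
  later overlapping ones) and copies of a single insertion-sequence element,
  placed uniformly or — for breakpoint-association checks — exactly at
  inversion boundaries.

Defaults describe the study conditions this package emulates: six genomes at
host GC 0.535, donor GC 0.12 below host, around five transfer events per
branch, insertion-sequence proliferation and inversions confined to one
sister pair, and branch lengths that put the closest pair near 98% nucleotide
identity, the next pair near 92%, and the outgroup beyond the reach of exact
16-mer matching. Chromosome length (150 kb) and gene count (150 families) are
scaled down from megabase genomes so a full clade simulates in about a
second; divergence levels, GC values, and rates are not scaled. What the
simulator deliberately does not model: indels, codon structure, rate
heterogeneity across sites, within-gene recombination, and gene loss (gene
content differences arise from acquisitions only). Tests passing on this
simulator therefore certify the *logic* of each analysis (thresholds, voting,
coordinate bookkeeping, statistics) — not robustness to alignment error or
annotation noise in real data.

`simulate_hit_table()` closes the loop for the transfer screen: for every
gene it draws a ranked homology-hit list whose taxonomy encodes the gene's
true status (see below), plus decoy hits strictly below the retention
thresholds and a self-genome hit, both of which the screen must discard. The
generator is built to be unambiguous, so the classifier is expected to
recover statuses with precision = recall = 1; that recovery is an acceptance
test, not a tautology — it fails if any rule (self-hit exclusion, ranking,
thresholds, strict majority, best-hit taxonomy) is implemented wrong.

## The transfer screen

`filter_hits()` retains hits whose high-scoring pairs cover at least 90% of
the query length and whose amino-acid similarity is at least 40%, after
removing subjects from the query's own genome. "Similarity" is the positives
percentage, not identity; both columns are carried. Ranks are recomputed by
descending bitscore with ties broken lexicographically by subject id, so
classification is deterministic.

`classify_genes()` votes over the top five retained hits: a gene is
*putatively acquired* when strictly more than half come from genera other
than the self genus (so exactly half is never acquired); among acquired
genes, those whose single best hit is from another genus are *recent*
acquisitions, the rest older ones. With fewer than five retained hits the
same strict-majority rule applies to what is available. A best hit lacking
genus-level taxonomy or flagged as metagenomic routes the gene to an
`ambiguous_taxonomy` bucket for manual examination — flagged by machine,
never auto-resolved. Hits whose genus is missing count as non-self in the
vote (they are, at any rate, not evidence of vertical descent). Donor
summaries group recent acquisitions by the best non-self hit's taxonomy:
same order as the self genome, other Cyanobacteria, Proteobacteria, other.
Functional summaries count COG letters, multi-letter assignments counting
once per letter, with an explicit unassigned bucket and both denominators
(all genes; genes with assignments) reported.

## Fragment-based ANI

`compute_ani()` follows the fragment-mapping design of k-mer ANI estimators:
the query is cut into consecutive non-overlapping 3,000-bp fragments
(trailing remainder discarded); each fragment is placed on the reference by
shared 16-mer voting (every shared k-mer votes for a diagonal on either
strand; the modal diagonal defines the candidate window); and identity is
estimated from the Jaccard index $j$ of the fragment's and window's k-mer
sets via the Mash relation

$$\mathrm{identity} = 1 + \frac{1}{k}\ln\frac{2j}{1+j}.$$

Placements below `min_identity` (default 80%) count as unmapped. Mappings are
made reciprocally consistent — each reference window is used by at most one
fragment, ties resolved by higher $j$ then lower query coordinate — standing
in for the orthologous-mapping filter of the published tool. ANI is the mean
identity over surviving mappings, reported with the mapped fraction (the
share of fragments that placed at all) and the conventional 95% same-species
call. Fragments more than 10% N are skipped; N-containing k-mers are dropped.
All k-mers vote rather than a minimizer subset: at the genome sizes this
package targets the index fits comfortably in memory, and using the full set
removes one approximation layer. The algorithm is asymmetric by construction;
on similar-length genomes the two directions agree within 0.5 points
(asserted as a property test, not assumed).

## Pangenome phyletics and the core-genome tree

`cluster_orthologs()` scores protein pairs by the Jaccard index of amino-acid
4-mer sets, draws reciprocal-best-hit edges between genomes plus same-genome
edges at least as strong as both members' best between-genome hit, and takes
connected components as clusters. This replaces Markov-clustering pipelines
with something self-contained and deterministic; it is adequate at simulator
scale (families are recovered exactly), but real-data cluster counts will
differ from what heavier clustering tools produce, and no acceptance claim is
made for them. Core clusters are present in every genome; single-copy core
clusters have exactly one member everywhere. `branch_unique_counts()` reports,
for every branch, the clusters present in all daughter leaves and absent
everywhere else (uniquely present) and the mirror image (uniquely absent) —
the "+/−" numbers drawn on pangenome phylogenies. The root has no branch: a
cluster "uniquely present at the root" is undefined without data beyond the
matrix.

`distance_tree()` concatenates the single-copy core families (equal lengths
guaranteed by the indel-free simulator; real data must arrive pre-aligned),
computes Poisson-corrected distances $d = -\ln(1-p)$ from per-site mismatch
fractions ($p$ capped at $1 - 10^{-9}$ for saturated pairs), and runs
neighbor joining, rooting on the outgroup. Support values are the percentage
of column-resampled bootstrap replicates whose NJ tree contains each
bipartition. Distance NJ deliberately stands in for maximum-likelihood
inference: the package's claim is phyletic accounting and topology recovery
(checked against the simulator's true tree, with all supports required at or
above 95% over 200 replicates), not likelihood optimization.

## GC landscape and the low-GC association test

`gc_windows()` computes GC fraction and GC skew $(G-C)/(G+C)$ in
non-overlapping windows (default 10 kb), excluding N from numerator and
denominator, wrapping the final window on circular chromosomes, and
accumulating the skew series from 0 at coordinate 0 so its global extrema —
the classical origin/terminus landmarks — are well defined with ties broken
toward coordinate zero.

The qualitative observation that low-GC islands coincide with recently
acquired genes is formalized as a permutation test. Low-GC windows are those
more than `threshold_sd` (default 1) standard deviations below the mean
window GC; the observed statistic is the fraction of recent-gene midpoints
inside them; and the null rotates all gene coordinates around the circular
chromosome by a uniform offset, preserving gene spacing and island
clustering — appropriate because transfers arrive in blocks. An independent
uniform re-placement null is available behind a flag for comparison. The
p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(1 + B)$, which
never returns zero.

The test's operating characteristics are checked under conditions chosen by
power analysis before freezing: a two-taxon clade (60 kb, 60 families) with
the acquisition rate set so recent genes are roughly 5% of all genes —
matching the acquisition intensity of the high-HGT genomes this package
emulates — and 600-bp analysis windows, the scale of a single gene, so
one-gene islands are not diluted. With full amelioration (statuses
independent of composition) the rejection rate at 0.05 stays within three
binomial standard errors of 0.05 over 200 replicate clades; with a 0.12 GC
offset and no amelioration, p ≤ 0.01 in at least 95% of 50 seeds. The
mid-range defaults (10-kb windows, 1 SD) are for exploratory landscape
description; the paper-scale correspondence is qualitative and no printed
effect size exists to match.

## Synteny anchors, breakpoints, and the mobilome

`find_anchors()` enumerates all maximal exact matches of length ≥ 20 bp on
both strands ("maxmatch" semantics — uniqueness is not required), by seeding
on exact `min_match_len`-mers, keeping only left-maximal seed hits (each
maximal match starts at exactly one), and extending right. The contract is
the maximal-match set itself, verified in tests against an exhaustive
diagonal-scanning oracle and by substring re-verification of every emitted
anchor. `cluster_anchors()` greedily chains colinear same-orientation anchors
with query and reference gaps within 500 bp (measured in the direction the
orientation implies, so crossing anchors never chain) and discards blocks
with less than 200 bp of anchored sequence — the published clustering floor.
Breakpoints are the boundaries between adjacent retained blocks in query
order, with orientation flips flagged as inversion breakpoints.
`mobilome_breakpoint_overlap()` quantifies the correspondence between
breakpoints and mobile-element annotations (fraction of breakpoints within a
2-kb margin of a feature, circular distances) with the same rotation null
and add-one p-value as the landscape test. Which annotation categories
constitute the mobilome is the caller's choice; the pipeline uses the
`mobile_element` feature kind.

## Numerical and interface conventions

* Internal coordinates are 0-based half-open everywhere; GFF3 and GenBank
  keep their native 1-based inclusive conventions on disk, converted exactly
  once in the readers/writers.
* Every stochastic routine takes an explicit seed, saves and restores the
  global RNG state, and is reproducible byte-for-byte: the pipeline writes
  identical output trees for identical (config, seed).
* Tie-breaks are fixed and documented: bitscore ties by subject id, fragment
  mapping ties by Jaccard then query coordinate, skew extrema ties by
  smallest coordinate, cluster ids by smallest member gene id.
* Degenerate inputs are first-class outcomes: genomes shorter than one
  fragment map nothing (with a warning), zero recent genes make the
  association test "undefined" rather than p = 1, saturated distances are
  capped, and empty donor summaries carry explicit zero counts.

## Problem sizes used by the test suite

Unit tests run on 12–60 kb simulated chromosomes; the acceptance checks use
the full default clade (150 kb, 150 families, six genomes), 200 bootstrap
replicates for the tree, 100 random phyletic matrices against exhaustive
enumeration, 50 sequence pairs against the exact-match oracle, and 200 null
plus 50 alternative clades for the permutation test. These sizes were chosen
so the entire suite certifies every contract in a few minutes while keeping
all statistical checks at the replicate counts stated above.

## Known limitations

Real-data ortholog counts and ANI values depend on the external tools and
database versions a study used; this package reproduces their *form* and
verifies its own implementations against truth and against brute-force
oracles, matching printed values only where the computation is fully
determined by deposited sequences. The screen consumes hit tables and does
not run homology searches itself. The NJ tree is a distance method: on very
short internal branches with little signal it can be less decisive than
likelihood methods, which is why bootstrap support is always reported.
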