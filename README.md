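# cladescope

Comparative genomics for small clades of closely related bacterial genomes,
built around the analyses a genome announcement of a thermophilic
cyanobacterium typically runs: horizontal-gene-transfer (HGT) screening,
average nucleotide identity (ANI), pangenome phyletics on a species tree, GC
landscape analysis, and exact-match synteny. A seeded clade simulator
generates annotated genomes with truth-labelled transfer events, so every
stage is tested end to end against known ground truth — no downloads needed.

**Who it is for:** microbial genomicists comparing a handful of complete
genomes within or around one genus, and method developers who want each
analysis step as a plain, deterministic, unit-tested R function rather than a
chain of external binaries.

## What it computes

* **HGT screen** (`filter_hits`, `classify_genes`, `summarize_donors`,
  `summarize_functions`): over a ranked protein homology-hit table with
  subject taxonomy, retain hits covering ≥ 90% of the query at ≥ 40%
  amino-acid similarity, then call a gene *putatively acquired* when strictly
  more than half of its top-five retained hits come from other genera, and
  *recently acquired* when the best hit itself is from another genus. Best
  hits without genus-level taxonomy or from metagenomic surveys are flagged
  for manual examination. Donor and COG-category summaries accompany the
  calls.
* **ANI** (`compute_ani`, `ani_matrix`): FastANI-style fragment mapping —
  3-kb query fragments placed by shared 16-mer voting, identity from the
  Jaccard index *j* via the Mash relation
  `identity = 1 + (1/k) ln(2j/(1+j))`, reciprocally consistent mappings,
  mapped-fraction reporting, and the conventional 95% same-species cutoff.
* **Pangenome phyletics** (`cluster_orthologs`, `core_and_single_copy`,
  `unique_per_genome`, `branch_unique_counts`): reciprocal-best-hit ortholog
  clusters, core and single-copy-core sets, per-genome unique clusters, and
  per-branch uniquely-present/absent counts (the "+/−" numbers on pangenome
  phylogenies).
* **Core-genome tree** (`concatenate_core`, `distance_tree`): neighbor
  joining on Poisson-corrected distances `d = −ln(1 − p)` from the
  concatenated single-copy core, rooted on an outgroup, with column-bootstrap
  support.
* **GC landscape** (`gc_windows`, `cumulative_skew_extrema`,
  `low_gc_hgt_association`): windowed GC and GC skew, cumulative-skew
  origin/terminus landmarks, and a circular-rotation permutation test of
  whether recently acquired genes concentrate in low-GC windows.
* **Synteny** (`find_anchors`, `cluster_anchors`, `breakpoints`,
  `mobilome_breakpoint_overlap`): all maximal exact matches on both strands
  (dot-plot coordinates), colinear block chaining with a 200-bp cluster
  floor, breakpoint detection with inversion flags, and a permutation test of
  breakpoint/mobile-element correspondence.
* **Simulator and pipeline** (`simulate_clade`, `simulate_hit_table`,
  `run_pipeline`): the generative model behind all tests, and one entry point
  that runs simulator → all stages → plain-text report bundle (TSV, BED,
  Newick, FASTA, GFF3, JSON manifest). A thin command-line wrapper lives at
  `inst/scripts/pipeline.R`.

## Worked example

```r
library(cladescope)

sim  <- simulate_clade(clade_config(seed = 42))     # six genomes + truth
tax  <- clade_taxonomy(names(sim$genomes))
hits <- simulate_hit_table(sim$truth$genes, tax, seed = 42)

calls <- classify_genes(hits, "Thermosynechococcus",
                        genes = sim$truth$genes$gene_id)
table(calls$status)
#>  acquired_other acquired_recent          native
#>              20              14             900
hgt_recovery_score(calls, sim$truth$genes)[c("precision", "recall")]
#> $precision [1] 1    $recall [1] 1

compute_ani(sim$genomes$CL1, sim$genomes$SCTE542)
#> ANI CL1 vs SCTE542: 92.0% (49/51 fragments mapped, 0.961), below species cutoff
compute_ani(sim$genomes$BP1, sim$genomes$NIES2134)
#> ANI BP1 vs NIES2134: 97.2% (48/54 fragments mapped, 0.889), same species (>= cutoff)

cl <- cluster_orthologs(sim$proteins)
core_and_single_copy(cl)$core |> length()
#> [1] 150
res <- distance_tree(concatenate_core(cl, sim$proteins),
                     outgroup = "SLIV", n_bootstrap = 200, seed = 42)
ape::write.tree(res$tree)
#> (((SCTE542:0.042,CL1:0.044)100:0.017,((BP1:0.010,NIES2134:0.011)100:0.021,
#>   NK55:0.030)100:0.032):0,SLIV:0.241)Root;
```

Reading the output: 934 genes received a status; the 14 recent acquisitions
are genes whose best homology hit lies outside the genus — exactly the genes
the simulator inserted on terminal branches (precision = recall = 1). The two
ANI calls straddle the 95% species cutoff the way the simulated branch
lengths dictate: the CL1–SCTE542 pair (~0.08 substitutions/site apart) sits
at 92%, below the cutoff, while the young BP1–NIES2134 pair sits above it
with a reduced mapped fraction caused by lineage-specific insertion-sequence
proliferation. The neighbor-joining tree recovers the true six-taxon topology
with 100% bootstrap support on every internal branch.

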