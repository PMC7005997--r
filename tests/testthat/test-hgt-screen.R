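mk_hits <- function(cov, sim, genus = "Thermosynechococcus",
                    query = "q1", metagenomic = FALSE) {
  n <- length(cov)
  data.frame(query_gene = query, query_genome = "G1",
             subject_id = sprintf("s%02d", seq_len(n)),
             subject_genome = NA_character_,
             subject_genus = rep_len(genus, n),
             subject_order = "Synechococcales", subject_phylum = "Cyanobacteria",
             metagenomic_flag = rep_len(metagenomic, n),
             percent_similarity = sim, percent_identity = sim - 5,
             hsp_query_cov = cov,
             bitscore = seq(500, by = -10, length.out = n),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

test_that("retention needs both coverage >= 0.90 and similarity >= 40", {
  h <- mk_hits(cov = c(0.95, 0.89, 0.90, 0.95, 0.50, 1.00),
               sim = c(55, 90, 40, 39.9, 80, 45))
  kept <- filter_hits(h)
  expect_identical(kept$subject_id, c("s01", "s03", "s06"))
  expect_identical(kept$rank, 1:3)
})

test_that("self-genome hits are removed before ranking", {
  h <- mk_hits(cov = rep(1, 3), sim = rep(80, 3))
  h$subject_genome <- c("G1", NA, "G2")
  kept <- filter_hits(h)
  expect_identical(kept$subject_id, c("s02", "s03"))
  expect_identical(kept$rank, 1:2)
})

test_that("tied bitscores rank by subject_id", {
  h <- mk_hits(cov = rep(1, 3), sim = rep(80, 3))
  h$bitscore <- c(100, 100, 100)
  h$subject_id <- c("zz", "aa", "mm")
  expect_identical(filter_hits(h)$subject_id, c("aa", "mm", "zz"))
})

test_that("voting rules reproduce every classification edge case", {
  self <- "Thermosynechococcus"
  # 5 hits, 3 non-self, best non-self -> recent acquisition
  h <- mk_hits(rep(1, 5), rep(80, 5),
               genus = c("Nostoc", "Nostoc", "Nostoc", self, self))
  expect_identical(classify_genes(h, self)$status, "acquired_recent")
  # 5 hits, 3 non-self, best self -> acquired but not recent
  h <- mk_hits(rep(1, 5), rep(80, 5),
               genus = c(self, "Nostoc", "Nostoc", "Nostoc", self))
  expect_identical(classify_genes(h, self)$status, "acquired_other")
  # exactly half non-self among 4 available hits -> native (strict majority)
  h <- mk_hits(rep(1, 4), rep(80, 4),
               genus = c(self, "Nostoc", "Nostoc", self))
  expect_identical(classify_genes(h, self)$status, "native")
  # exactly half of top-five replaced by decoys below threshold: 2 of 4 left
  h <- mk_hits(rep(1, 5), c(80, 80, 80, 80, 30),
               genus = c(self, "Nostoc", "Nostoc", self, "Nostoc"))
  expect_identical(classify_genes(h, self)$status, "native")
  # metagenomic best hit -> flagged for manual examination
  h <- mk_hits(rep(1, 5), rep(80, 5), genus = "Nostoc")
  h$metagenomic_flag[1] <- TRUE
  expect_identical(classify_genes(h, self)$status, "ambiguous_taxonomy")
  # best hit without genus assignment -> same bucket
  h <- mk_hits(rep(1, 5), rep(80, 5),
               genus = c(NA, self, self, self, self))
  expect_identical(classify_genes(h, self)$status, "ambiguous_taxonomy")
  # nothing retained -> no_homologs
  h <- mk_hits(rep(0.5, 3), rep(80, 3))
  expect_identical(classify_genes(h, self)$status, "no_homologs")
})

test_that("statuses partition the gene universe", {
  sim <- simulate_clade(tiny_clade_config(seed = 21))
  tax <- clade_taxonomy(names(sim$genomes))
  hits <- simulate_hit_table(sim$truth$genes, tax, seed = 21)
  calls <- classify_genes(hits, "Thermosynechococcus",
                          genes = sim$truth$genes$gene_id)
  expect_equal(nrow(calls), nrow(sim$truth$genes))
  expect_equal(anyDuplicated(calls$gene_id), 0L)
  expect_true(all(calls$status %in% c("native", "acquired_recent",
                                      "acquired_other", "ambiguous_taxonomy",
                                      "no_homologs")))
  # acquired implies a strict non-self majority in the vote
  acq <- calls[calls$status %in% c("acquired_recent", "acquired_other"), ]
  expect_true(all(acq$n_top5_other_genus * 2 > pmin(acq$n_retained_hits, 5)))
})

test_that("raising min_similarity never increases retained or acquired counts", {
  sim <- simulate_clade(tiny_clade_config(seed = 22))
  tax <- clade_taxonomy(names(sim$genomes))
  hits <- simulate_hit_table(sim$truth$genes, tax, seed = 22)
  prev_kept <- Inf; prev_acq <- Inf
  for (ms in c(40, 60, 80, 94)) {
    kept <- nrow(filter_hits(hits, min_similarity = ms))
    calls <- classify_genes(hits, "Thermosynechococcus", min_similarity = ms)
    acq <- sum(calls$status %in% c("acquired_recent", "acquired_other"))
    expect_lte(kept, prev_kept); expect_lte(acq, prev_acq)
    prev_kept <- kept; prev_acq <- acq
  }
})

test_that("donor summaries recover the configured donor mixture exactly", {
  calls <- data.frame(
    gene_id = sprintf("g%02d", 1:10), status = "acquired_recent",
    donor_genus = "x",
    donor_order = c(rep("Synechococcales", 5), rep("Nostocales", 3),
                    rep("Pseudomonadales", 2)),
    donor_phylum = c(rep("Cyanobacteria", 8), rep("Proteobacteria", 2)),
    stringsAsFactors = FALSE)
  s <- summarize_donors(calls)
  expect_equal(s$fraction[s$group == "self_order"], 0.5)
  expect_equal(s$fraction[s$group == "other_cyanobacteria"], 0.3)
  expect_equal(s$fraction[s$group == "Proteobacteria"], 0.2)
  expect_equal(sum(s$count), 10L)

  all_proteo <- calls; all_proteo$donor_order <- "Pseudomonadales"
  all_proteo$donor_phylum <- "Proteobacteria"
  s2 <- summarize_donors(all_proteo)
  expect_equal(s2$fraction[s2$group == "Proteobacteria"], 1.0)

  s3 <- summarize_donors(calls[0, ])
  expect_equal(sum(s3$count), 0L)
  expect_true(all(is.na(s3$fraction)))
})

test_that("functional tallies count per letter with an unassigned bucket", {
  ann <- gene_table(locus_tag = c("a", "b", "c", "d"),
                    start = c(0L, 10L, 20L, 30L), end = c(9L, 19L, 29L, 39L),
                    strand = rep("+", 4), feature_kind = rep("CDS", 4),
                    cog_category = c("P", "P", "E", NA))
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      stringsAsFactors = FALSE)
  s <- summarize_functions(calls, ann)
  expect_equal(s$per_letter$count[s$per_letter$cog == "P"], 2L)
  expect_equal(s$per_letter$count[s$per_letter$cog == "E"], 1L)
  expect_equal(s$n_unassigned, 1L)
  # multi-letter assignment contributes to each letter
  ann$cog_category[3] <- "EP"
  s2 <- summarize_functions(calls, ann)
  expect_equal(s2$per_letter$count[s2$per_letter$cog == "P"], 3L)
  expect_equal(s2$per_letter$count[s2$per_letter$cog == "E"], 1L)
  expect_error(summarize_functions(data.frame(gene_id = "zz"), ann), "zz")
})
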