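rand_protein <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]], n, TRUE),
                                  collapse = "")

test_that("perfect one-to-one families cluster pairwise across genomes", {
  set.seed(51)
  base <- replicate(3, rand_protein(120))
  proteins <- list(gA = setNames(base, c("gA_1", "gA_2", "gA_3")),
                   gB = setNames(base, c("gB_1", "gB_2", "gB_3")))
  cl <- cluster_orthologs(proteins)
  expect_equal(nrow(cl$phyletic_matrix), 3L)
  expect_true(all(cl$phyletic_matrix == 1L))
})

test_that("a single genome of unrelated proteins yields singleton clusters", {
  set.seed(52)
  proteins <- list(gA = setNames(replicate(5, rand_protein(150)),
                                 paste0("gA_", 1:5)))
  cl <- cluster_orthologs(proteins)
  expect_equal(nrow(cl$phyletic_matrix), 5L)
})

test_that("simulated families are recovered exactly as clusters", {
  sim <- simulate_clade(tiny_clade_config(seed = 53))
  cl <- cluster_orthologs(sim$proteins)
  got <- merge(cl$membership, sim$families,
               by.x = c("gene_id", "genome_id"),
               by.y = c("locus_tag", "genome_id"))
  expect_equal(nrow(got), nrow(cl$membership))
  # clusters and true families induce the same partition of genes
  tab <- table(got$cluster, got$family)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("core and single-copy-core match a brute-force scan", {
  set.seed(54)
  for (rep in 1:5) {
    pm <- random_phyletic(50, sprintf("G%d", 1:6))
    got <- core_and_single_copy(pm)
    core <- rownames(pm)[apply(pm, 1, function(r) all(r >= 1))]
    scc <- rownames(pm)[apply(pm, 1, function(r) all(r == 1))]
    expect_setequal(got$core, core)
    expect_setequal(got$single_copy_core, scc)
    expect_true(all(got$single_copy_core %in% got$core))
  }
  # spot cases: one genome missing, one duplicated
  pm <- matrix(c(1, 1, 1, 1, 1, 0,
                 1, 1, 1, 1, 1, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("c1", "c2"), sprintf("G%d", 1:6)))
  got <- core_and_single_copy(pm)
  expect_identical(got$core, "c2")
  expect_identical(got$single_copy_core, character(0))
})

test_that("unique-per-genome counts match a brute-force scan", {
  set.seed(55)
  pm <- random_phyletic(80, sprintf("G%d", 1:6))
  got <- unique_per_genome(pm)
  for (g in colnames(pm)) {
    expected <- sum(pm[, g] > 0 & rowSums(pm[, colnames(pm) != g]) == 0)
    expect_equal(unname(got[g]), expected)
  }
  expect_equal(unname(unique_per_genome(pm * 0)), rep(0L, 6))
})

test_that("branch counts equal exhaustive subset enumeration", {
  tr <- "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);"
  set.seed(56)
  for (rep in 1:10) {
    pm <- random_phyletic(100, LETTERS[1:6])
    got <- branch_unique_counts(tr, pm)
    want <- brute_branch_counts(tr, pm)
    m <- merge(got, want, by = "branch")
    expect_equal(nrow(m), nrow(got))
    expect_equal(m$n_uniquely_present.x, m$n_uniquely_present.y)
    expect_equal(m$n_uniquely_absent.x, m$n_uniquely_absent.y)
  }
})

test_that("single-leaf presence and absence land on the right branch", {
  tr <- "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);"
  pm <- matrix(0L, nrow = 2, ncol = 6,
               dimnames = list(c("only_A", "all_but_A"), LETTERS[1:6]))
  pm["only_A", "A"] <- 1L
  pm["all_but_A", ] <- 1L; pm["all_but_A", "A"] <- 0L
  bc <- branch_unique_counts(tr, pm)
  a_row <- bc[bc$branch == "A", ]
  expect_equal(a_row$n_uniquely_present, 1L)
  expect_equal(a_row$n_uniquely_absent, 1L)
  expect_equal(sum(bc$n_uniquely_present), 1L)
  expect_error(branch_unique_counts("((A:1,B:1):1,Z:1);", pm), "mismatch")
})

test_that("uniquely-present counts over leaves never exceed cluster count", {
  set.seed(57)
  pm <- random_phyletic(60, LETTERS[1:6])
  bc <- branch_unique_counts("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);", pm)
  leafs <- bc[bc$n_leaves == 1, ]
  expect_lte(sum(leafs$n_uniquely_present), nrow(pm))
})

test_that("concatenation sums family lengths and rejects ragged input", {
  set.seed(58)
  p1 <- rand_protein(10); p2 <- rand_protein(15)
  proteins <- list(gA = setNames(c(p1, p2), c("gA_1", "gA_2")),
                   gB = setNames(c(p1, p2), c("gB_1", "gB_2")))
  cl <- cluster_orthologs(proteins, min_jaccard = 0.9)
  sm <- concatenate_core(cl, proteins)
  expect_equal(sm$n_sites, 25L)
  expect_error(concatenate_core(cl, proteins, cluster_ids = character(0)),
               "no families")
  proteins$gB[[2]] <- rand_protein(14)
  expect_error(concatenate_core(cl, proteins), "ragged")
})

test_that("four taxa with near-additive distances give the unique topology", {
  set.seed(61)
  a <- rand_protein(400)
  flip <- function(s, pos) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v[pos] <- vapply(v[pos], function(x)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "")
    paste(v, collapse = "")
  }
  b <- flip(a, 1:6)                 # A-B close
  c_ <- flip(a, 101:180)            # C far from (A,B)
  d_ <- flip(c_, 301:312)           # D close to C
  seqs <- c(A = a, B = b, C = c_, D = d_)
  res <- distance_tree(seqs, outgroup = "D", n_bootstrap = 20, seed = 1)
  expect_equal(phangorn::RF.dist(ape::unroot(res$tree),
                                 ape::read.tree(text = "((A,B),(C,D));")), 0)
  # identical pair -> zero corrected distance -> zero terminal branches
  seqs2 <- c(A = a, B = a, C = c_, D = d_)
  res2 <- distance_tree(seqs2, outgroup = "D", n_bootstrap = 5, seed = 1)
  tipA <- which(res2$tree$tip.label == "A")
  eA <- res2$tree$edge.length[res2$tree$edge[, 2] == tipA]
  expect_equal(eA, 0, tolerance = 1e-12)
})

test_that("distance tree recovers the simulated topology with full support", {
  sim <- simulate_clade(tiny_clade_config(seed = 59, genome_length = 60000L,
                                          n_gene_families = 60L))
  cl <- cluster_orthologs(sim$proteins)
  sm <- concatenate_core(cl, sim$proteins)
  res <- distance_tree(sm, outgroup = "SLIV", n_bootstrap = 100, seed = 59)
  expect_equal(ape::dist.topo(ape::unroot(res$tree), ape::unroot(sim$tree)), 0,
               ignore_attr = TRUE)
  expect_true(all(res$support >= 95))
})

test_that("tree inference is invariant to taxon input order", {
  sim <- simulate_clade(tiny_clade_config(seed = 60))
  cl <- cluster_orthologs(sim$proteins)
  sm <- concatenate_core(cl, sim$proteins)
  res1 <- distance_tree(sm, outgroup = "SLIV", n_bootstrap = 20, seed = 1)
  sm2 <- sm; sm2$sequences <- rev(sm2$sequences)
  res2 <- distance_tree(sm2, outgroup = "SLIV", n_bootstrap = 20, seed = 1)
  expect_equal(ape::dist.topo(ape::unroot(res1$tree), ape::unroot(res2$tree)),
               0, ignore_attr = TRUE)
})

test_that("identical sequences warn of a star-like tree and zero distances", {
  seqs <- setNames(rep(rand_protein(60), 3), c("A", "B", "C"))
  expect_warning(res <- distance_tree(seqs, outgroup = "C", n_bootstrap = 5,
                                      seed = 1), "star")
  expect_true(all(res$tree$edge.length <= 1e-12))
})
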