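test_that("identity and reverse-complement pairs give single full anchors", {
  set.seed(81)
  s <- rand_seq(1000)
  a <- find_anchors(s, s, 20)
  fw <- a[a$orientation == "forward", ]
  expect_true(any(fw$q_start == 0 & fw$q_end == 1000 &
                    fw$r_start == 0 & fw$r_end == 1000))
  b <- find_anchors(s, reverse_complement(s), 20)
  rv <- b[b$orientation == "reverse", ]
  expect_true(any(rv$q_start == 0 & rv$q_end == 1000 &
                    rv$r_start == 0 & rv$r_end == 1000))
})

test_that("a planted shared segment is found exactly once", {
  set.seed(82)
  seg <- rand_seq(300)
  # flanks chosen so the planted match cannot extend by chance
  q <- paste0(rand_seq(1999), "A", seg, "A", rand_seq(2699))
  r <- paste0(rand_seq(999), "C", seg, "C", rand_seq(3699))
  a <- find_anchors(q, r, 50)
  expect_equal(nrow(a), 1L)
  expect_equal(a$q_start, 2000L); expect_equal(a$q_end, 2300L)
  expect_equal(a$r_start, 1000L); expect_equal(a$r_end, 1300L)
  expect_identical(a$orientation, "forward")
  expect_identical(anchor_key(a), anchor_key(brute_mems(q, r, 50)))
})

test_that("every emitted anchor passes substring re-verification", {
  set.seed(83)
  base <- rand_seq(1500)
  q <- substitute_seq(base, 0.05)
  r <- substitute_seq(base, 0.05)
  a <- find_anchors(q, r, 15)
  expect_gt(nrow(a), 5)
  for (i in seq_len(nrow(a))) {
    qs <- substr(q, a$q_start[i] + 1, a$q_end[i])
    rs <- substr(r, a$r_start[i] + 1, a$r_end[i])
    if (a$orientation[i] == "reverse") rs <- reverse_complement(rs)
    expect_identical(qs, rs)
  }
})

test_that("anchor sets match the exhaustive diagonal-scan oracle", {
  set.seed(84)
  for (rep in 1:5) {
    base <- rand_seq(sample(800:1500, 1))
    q <- substitute_seq(base, 0.04)
    r <- substitute_seq(base, 0.04)
    expect_identical(anchor_key(find_anchors(q, r, 18)),
                     anchor_key(brute_mems(q, r, 18)))
  }
})

test_that("anchors are symmetric under query/reference exchange", {
  set.seed(85)
  base <- rand_seq(1200)
  q <- substitute_seq(base, 0.05)
  r <- substitute_seq(base, 0.05)
  a <- find_anchors(q, r, 15)
  b <- find_anchors(r, q, 15)
  swapped <- data.frame(q_start = b$r_start, q_end = b$r_end,
                        r_start = b$q_start, r_end = b$q_end,
                        orientation = b$orientation)
  expect_identical(anchor_key(a), anchor_key(swapped))
})

test_that("chaining keeps colinear anchors and drops short blocks", {
  two <- data.frame(q_start = c(0L, 250L), q_end = c(150L, 400L),
                    r_start = c(0L, 250L), r_end = c(150L, 400L),
                    orientation = "forward", length = c(150L, 150L))
  b <- cluster_anchors(two, min_cluster_len = 200, max_gap = 500)
  expect_equal(nrow(b), 1L)
  expect_equal(b$anchored_len, 300L)
  one <- two[1, ]
  expect_equal(nrow(cluster_anchors(one, 200, 500)), 0L)
  # crossing anchors are never chained
  crossing <- data.frame(q_start = c(0L, 250L), q_end = c(150L, 400L),
                         r_start = c(600L, 0L), r_end = c(750L, 150L),
                         orientation = "forward", length = c(150L, 150L))
  bc <- cluster_anchors(crossing, min_cluster_len = 100, max_gap = 500)
  expect_equal(nrow(bc), 2L)
})

test_that("breakpoints appear between blocks and flag orientation flips", {
  blocks1 <- data.frame(q_start = 0L, q_end = 5000L, r_start = 0L,
                        r_end = 5000L, orientation = "forward",
                        n_anchors = 3L, anchored_len = 4000L)
  expect_equal(nrow(breakpoints(blocks1)), 0L)
  blocks2 <- rbind(blocks1,
                   data.frame(q_start = 5200L, q_end = 9000L, r_start = 5200L,
                              r_end = 9000L, orientation = "reverse",
                              n_anchors = 2L, anchored_len = 3000L))
  bp <- breakpoints(blocks2)
  expect_equal(nrow(bp), 1L)
  expect_true(bp$inversion)
  expect_equal(bp$pos, 5000L)
})

test_that("planted inversions produce flip breakpoints near their boundaries", {
  cfg <- tiny_clade_config(seed = 86, genome_length = 60000L,
                           n_gene_families = 60L,
                           tree = "(P:0.001,Q:0.001);", outgroup = "Q",
                           hgt_rate = 0,
                           n_inversions = c(P = 3L),
                           is_element = list(length = 800L, copies = NULL))
  sim <- simulate_clade(cfg)
  q <- sim$genomes[["P"]]; r <- sim$genomes[["Q"]]
  inv <- sim$truth$inversions
  expect_equal(nrow(inv), 3L)
  a <- find_anchors(q, r, 20)
  blocks <- cluster_anchors(a, min_cluster_len = 200, max_gap = 500)
  bp <- breakpoints(blocks, nchar(q$sequence))
  flips <- bp$pos[bp$inversion]
  bounds <- sort(unique(c(inv$start, inv$end)))
  expect_gte(length(flips), 2L)
  for (f in flips) expect_lte(min(abs(f - bounds)), 500)
})

test_that("mobilome/breakpoint overlap hits 1.0 when elements sit at flips", {
  cfg <- tiny_clade_config(seed = 87, genome_length = 60000L,
                           n_gene_families = 60L,
                           tree = "(P:0.001,Q:0.001);", outgroup = "Q",
                           hgt_rate = 0, is_at_breakpoints = TRUE,
                           n_inversions = c(P = 2L),
                           is_element = list(length = 800L, copies = c(P = 4L)))
  sim <- simulate_clade(cfg)
  q <- sim$genomes[["P"]]; r <- sim$genomes[["Q"]]
  a <- find_anchors(q, r, 20)
  blocks <- cluster_anchors(a, 200, 500)
  bp <- breakpoints(blocks, nchar(q$sequence))
  mob <- q$annotations[q$annotations$feature_kind == "mobile_element", ]
  ov <- mobilome_breakpoint_overlap(bp, mob, nchar(q$sequence),
                                    margin = 2000, n_perm = 99, seed = 1)
  expect_true(ov$defined)
  expect_equal(ov$observed, 1.0)
  expect_lt(ov$p_value, 0.2)
})

test_that("overlap test reports undefined without mobilome features", {
  bp <- data.frame(pos = c(100L, 500L), left_orientation = "forward",
                   right_orientation = "reverse", inversion = TRUE)
  mob <- data.frame(start = integer(), end = integer())
  ov <- mobilome_breakpoint_overlap(bp, mob, 10000L)
  expect_false(ov$defined)
  expect_equal(ov$observed, 0)
})
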