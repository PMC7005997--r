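# Small configs and independent brute-force oracles shared across tests.

tiny_clade_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(genome_length = 30000L, n_gene_families = 30L,
                   is_element = list(length = 800L,
                                     copies = c(BP1 = 3L, NIES2134 = 3L)),
                   n_inversions = c(BP1 = 1L, NIES2134 = 1L), seed = seed)
  defaults[names(args)] <- args
  do.call(clade_config, defaults)
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

substitute_seq <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  idx <- which(runif(length(v)) < rate)
  if (length(idx)) {
    m <- match(v[idx], bases)
    v[idx] <- bases[((m - 1L + sample.int(3L, length(idx), TRUE)) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# Maximal exact matches by exhaustive diagonal scanning (run-length encoding
# of per-diagonal equality vectors); independent of the seed-and-extend path.
brute_mems <- function(q, r, min_len) {
  qv <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  out <- list()
  scan <- function(rv2, orientation, nr_orig) {
    nq <- length(qv); nr <- length(rv2)
    for (d in (-(nq - 1L)):(nr - 1L)) {   # d = rpos - qpos (1-based)
      qidx <- max(1L, 1L - d):min(nq, nr - d)
      if (length(qidx) < min_len) next
      eq <- qv[qidx] == rv2[qidx + d]
      rl <- rle(eq)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (i in which(rl$values & rl$lengths >= min_len)) {
        q0 <- qidx[1L] + starts[i] - 2L    # 0-based query start
        len <- rl$lengths[i]
        r0 <- q0 + d                       # 0-based start in scanned strand
        if (orientation == "forward") {
          out[[length(out) + 1L]] <<- data.frame(
            q_start = q0, q_end = q0 + len, r_start = r0, r_end = r0 + len,
            orientation = "forward", length = len)
        } else {
          out[[length(out) + 1L]] <<- data.frame(
            q_start = q0, q_end = q0 + len, r_start = nr_orig - (r0 + len),
            r_end = nr_orig - r0, orientation = "reverse", length = len)
        }
      }
    }
  }
  rv <- strsplit(toupper(r), "", fixed = TRUE)[[1]]
  scan(rv, "forward", length(rv))
  scan(strsplit(reverse_complement(r), "", fixed = TRUE)[[1]], "reverse",
       length(rv))
  if (!length(out))
    return(data.frame(q_start = integer(), q_end = integer(),
                      r_start = integer(), r_end = integer(),
                      orientation = character(), length = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$q_start, res$r_start, res$orientation), ]
  rownames(res) <- NULL
  res
}

anchor_key <- function(a)
  sort(sprintf("%d:%d:%d:%d:%s", a$q_start, a$q_end, a$r_start, a$r_end,
               a$orientation))

# Exhaustive enumeration of uniquely-present/absent counts per branch:
# matches each cluster's presence pattern against every clade leaf set.
brute_branch_counts <- function(tree, pm) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  present <- pm[, tree$tip.label, drop = FALSE] > 0
  ntip <- length(tree$tip.label)
  sets <- lapply(tree$edge[, 2], function(child)
    if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label)
  data.frame(
    branch = vapply(sets, function(s) paste(sort(s), collapse = "|"), ""),
    n_uniquely_present = vapply(sets, function(s) {
      sum(apply(present, 1, function(row)
        setequal(colnames(present)[row], s)))
    }, 0),
    n_uniquely_absent = vapply(sets, function(s) {
      sum(apply(present, 1, function(row)
        setequal(colnames(present)[!row], s)))
    }, 0),
    stringsAsFactors = FALSE)
}

random_phyletic <- function(n_clusters, genomes, p_present = 0.5,
                            max_copies = 2L) {
  m <- matrix(rbinom(n_clusters * length(genomes), 1, p_present) *
                sample.int(max_copies, n_clusters * length(genomes), TRUE),
              nrow = n_clusters,
              dimnames = list(sprintf("C%03d", seq_len(n_clusters)), genomes))
  m
}

# Best placement of a fragment on a reference by exhaustive Hamming scanning
# over every window start on both strands.
brute_best_window <- function(fragment, ref) {
  fv <- strsplit(fragment, "", fixed = TRUE)[[1]]
  W <- length(fv)
  best <- list(identity = -1, ref_start = NA, strand = NA)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") ref else reverse_complement(ref)
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    for (st in 0:(length(sv) - W)) {
      id <- mean(fv == sv[(st + 1):(st + W)])
      if (id > best$identity) {
        fs <- if (strand == "+") st else length(sv) - (st + W)
        best <- list(identity = id, ref_start = fs, strand = strand)
      }
    }
  }
  best
}
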