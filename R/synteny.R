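#' @importFrom graphics plot segments
NULL

mem_one_strand <- function(qv, rv, min_len) {
  nq <- length(qv); nr <- length(rv)
  if (nq < min_len || nr < min_len) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      r_start = integer(), r_end = integer()))
  }
  q <- paste(qv, collapse = ""); r <- paste(rv, collapse = "")
  qseed <- substring(q, 1:(nq - min_len + 1L), min_len:nq)
  rseed <- substring(r, 1:(nr - min_len + 1L), min_len:nr)
  dq <- data.table::data.table(seed = qseed, qpos = seq_along(qseed))
  dr <- data.table::data.table(seed = rseed, rpos = seq_along(rseed))
  hits <- merge(dq, dr, by = "seed", allow.cartesian = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      r_start = integer(), r_end = integer()))
  }
  # keep only left-maximal seed hits: each maximal match starts at exactly one
  left_max <- hits$qpos == 1L | hits$rpos == 1L |
    qv[pmax(hits$qpos - 1L, 1L)] != rv[pmax(hits$rpos - 1L, 1L)]
  hits <- hits[left_max]
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    qp <- hits$qpos[i]; rp <- hits$rpos[i]
    len <- min_len
    while (qp + len <= nq && rp + len <= nr && qv[qp + len] == rv[rp + len])
      len <- len + 1L
    out[[i]] <- c(qp - 1L, qp - 1L + len, rp - 1L, rp - 1L + len)
  }
  m <- unique(do.call(rbind, out))
  data.frame(q_start = m[, 1], q_end = m[, 2], r_start = m[, 3],
             r_end = m[, 4])
}

#' Find all maximal exact matches between two genomes
#'
#' Enumerates every maximal exact match of length at least `min_match_len` on
#' both strands ("maxmatch" semantics: matches need not be unique in either
#' genome). A match is maximal when extending it by one base in either
#' direction breaks the equality or crosses a sequence boundary. Coordinates
#' are 0-based half-open on the forward strands of both genomes; for reverse
#' orientation the query substring equals the reverse complement of the
#' reference substring.
#'
#' @param query,ref [genome()] objects or DNA strings.
#' @param min_match_len Minimum match length (bp).
#' @return data.frame: q_start, q_end, r_start, r_end, orientation
#'   (`"forward"`/`"reverse"`), length.
#' @export
find_anchors <- function(query, ref, min_match_len = 20L) {
  qs <- if (inherits(query, "genome")) query$sequence else toupper(query)
  rs <- if (inherits(ref, "genome")) ref$sequence else toupper(ref)
  if (nchar(qs) == 0L || nchar(rs) == 0L) stop("empty sequence")
  qv <- strsplit(qs, "", fixed = TRUE)[[1]]
  rv <- strsplit(rs, "", fixed = TRUE)[[1]]
  fwd <- mem_one_strand(qv, rv, min_match_len)
  fwd$orientation <- rep("forward", nrow(fwd))
  rcv <- strsplit(reverse_complement(rs), "", fixed = TRUE)[[1]]
  rev <- mem_one_strand(qv, rcv, min_match_len)
  if (nrow(rev)) {
    nr <- length(rv)
    tmp <- rev
    rev$r_start <- nr - tmp$r_end
    rev$r_end <- nr - tmp$r_start
  }
  rev$orientation <- rep("reverse", nrow(rev))
  out <- rbind(fwd, rev)
  out$length <- out$q_end - out$q_start
  out <- out[order(out$q_start, out$r_start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain colinear anchors into synteny blocks
#'
#' Greedy chaining of same-orientation anchors sorted by query start: an
#' anchor joins the open block when both its query gap and its reference gap
#' to the block's last anchor lie within `max_gap` (reference gaps measured in
#' the direction implied by the orientation, so crossing anchors are never
#' chained). Blocks whose total anchored length falls below `min_cluster_len`
#' are discarded.
#'
#' @param anchors Output of [find_anchors()].
#' @param min_cluster_len Minimum total anchored length per block (bp).
#' @param max_gap Maximum gap between chained anchors (bp).
#' @return data.frame of blocks: q_start, q_end, r_start, r_end, orientation,
#'   n_anchors, anchored_len.
#' @export
cluster_anchors <- function(anchors, min_cluster_len = 200L, max_gap = 500L) {
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      r_start = integer(), r_end = integer(),
                      orientation = character(), n_anchors = integer(),
                      anchored_len = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L) return(empty)
  blocks <- list()
  for (ori in unique(anchors$orientation)) {
    a <- anchors[anchors$orientation == ori, , drop = FALSE]
    a <- a[order(a$q_start, a$r_start), , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      data.frame(q_start = cur$q_start, q_end = cur$q_end,
                 r_start = cur$r_start, r_end = cur$r_end,
                 orientation = ori, n_anchors = cur$n,
                 anchored_len = cur$len, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(a))) {
      x <- a[i, ]
      if (!is.null(cur)) {
        q_gap <- x$q_start - cur$last_q_end
        r_gap <- if (ori == "forward") x$r_start - cur$last_r_end
                 else cur$last_r_start - x$r_end
        if (abs(q_gap) <= max_gap && abs(r_gap) <= max_gap) {
          cur$q_end <- max(cur$q_end, x$q_end)
          cur$r_start <- min(cur$r_start, x$r_start)
          cur$r_end <- max(cur$r_end, x$r_end)
          cur$last_q_end <- x$q_end
          cur$last_r_end <- x$r_end; cur$last_r_start <- x$r_start
          cur$n <- cur$n + 1L; cur$len <- cur$len + x$length
          next
        }
        blocks[[length(blocks) + 1L]] <- flush(cur)
      }
      cur <- list(q_start = x$q_start, q_end = x$q_end, r_start = x$r_start,
                  r_end = x$r_end, last_q_end = x$q_end,
                  last_r_end = x$r_end, last_r_start = x$r_start,
                  n = 1L, len = x$length)
    }
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur)
  }
  out <- do.call(rbind, blocks)
  out <- out[out$anchored_len >= min_cluster_len, , drop = FALSE]
  out <- out[order(out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  if (is.null(out)) empty else out
}

#' Synteny breakpoints on the query
#'
#' Boundaries between adjacent retained blocks after sorting by query start;
#' a boundary where block orientation changes is flagged as an inversion
#' breakpoint.
#'
#' @param blocks Output of [cluster_anchors()].
#' @param query_length Query genome length (bp); retained for BED export.
#' @return data.frame: pos (query bp at the end of the left block),
#'   left_orientation, right_orientation, inversion (logical).
#' @export
breakpoints <- function(blocks, query_length = NA_integer_) {
  if (nrow(blocks) < 2L)
    return(data.frame(pos = integer(), left_orientation = character(),
                      right_orientation = character(), inversion = logical(),
                      stringsAsFactors = FALSE))
  b <- blocks[order(blocks$q_start), , drop = FALSE]
  n <- nrow(b)
  data.frame(pos = b$q_end[-n],
             left_orientation = b$orientation[-n],
             right_orientation = b$orientation[-1],
             inversion = b$orientation[-n] != b$orientation[-1],
             stringsAsFactors = FALSE)
}

#' Do synteny breakpoints coincide with mobile genetic elements?
#'
#' Reports the fraction of breakpoints lying within `margin` bp of a mobilome
#' feature (distances on the circular chromosome) and a permutation p-value
#' from rotating the mobilome annotation by a uniform random offset, the same
#' null as in [low_gc_hgt_association()].
#'
#' @param bps Output of [breakpoints()].
#' @param mobilome data.frame with `start`, `end` (0-based half-open) of
#'   mobile-element features.
#' @param genome_length Query genome length (bp).
#' @param margin Distance tolerance (bp).
#' @param n_perm,seed Permutation settings.
#' @return List: observed (fraction), p_value, n_breakpoints, n_features,
#'   defined (FALSE when either side is empty).
#' @export
mobilome_breakpoint_overlap <- function(bps, mobilome, genome_length,
                                        margin = 2000L, n_perm = 1000L,
                                        seed = 1L) {
  if (nrow(bps) == 0L || nrow(mobilome) == 0L)
    return(list(observed = if (nrow(bps)) 0 else NA_real_, p_value = NA_real_,
                n_breakpoints = nrow(bps), n_features = nrow(mobilome),
                defined = FALSE))
  L <- genome_length
  near <- function(pos, starts, ends) {
    vapply(pos, function(p) {
      d1 <- (p - ends) %% L      # downstream distance feature end -> p
      d2 <- (starts - p) %% L    # upstream distance p -> feature start
      inside <- ifelse(ends >= starts, p >= starts & p < ends,
                       p >= starts | p < ends)  # features may wrap after rotation
      any(pmin(d1, d2) <= margin | inside)
    }, TRUE)
  }
  obs <- mean(near(bps$pos, mobilome$start, mobilome$end))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(b) {
    off <- sample.int(L, 1L)
    mean(near(bps$pos, (mobilome$start + off) %% L, (mobilome$end + off) %% L))
  }, 0)
  list(observed = obs,
       p_value = (1 + sum(null_stats >= obs)) / (1 + n_perm),
       n_breakpoints = nrow(bps), n_features = nrow(mobilome), defined = TRUE)
}

#' Dot plot of synteny anchors (base graphics)
#'
#' @param anchors Output of [find_anchors()].
#' @param ... Passed to [plot()].
#' @export
plot_anchors <- function(anchors, ...) {
  plot(NA, xlim = range(c(anchors$q_start, anchors$q_end)),
       ylim = range(c(anchors$r_start, anchors$r_end)),
       xlab = "query (bp)", ylab = "reference (bp)", ...)
  fw <- anchors$orientation == "forward"
  segments(anchors$q_start[fw], anchors$r_start[fw], anchors$q_end[fw],
           anchors$r_end[fw], col = "red")
  segments(anchors$q_start[!fw], anchors$r_end[!fw], anchors$q_end[!fw],
           anchors$r_start[!fw], col = "blue")
  invisible(anchors)
}
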