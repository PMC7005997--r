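#' Windowed GC content and GC skew
#'
#' Computes per-window GC fraction and GC skew (G - C)/(G + C) over windows of
#' `window_len` every `step` bp, plus the cumulative skew series (prefixed
#' with 0 at coordinate 0). N bases are excluded from both numerator and
#' denominator; windows with an empty denominator are flagged undefined. For a
#' circular genome the final window wraps around the origin so that windows
#' cover every base; for a linear genome the final window is truncated.
#'
#' @param genome A [genome()] or DNA string.
#' @param window_len Window length (bp), >= 1.
#' @param step Step between window starts (bp), > 0.
#' @return A `window_track` list: `windows` data.frame (start, gc, skew,
#'   gc_defined), `cumulative_skew`, `window_len`, `step`, `genome_length`,
#'   `circular`, `mean_gc` (whole-genome, N-excluded).
#' @export
gc_windows <- function(genome, window_len = 10000L, step = window_len) {
  if (step <= 0L) stop("step must be positive")
  if (window_len < 1L) stop("window_len must be >= 1")
  s <- if (inherits(genome, "genome")) genome$sequence else toupper(genome)
  circular <- if (inherits(genome, "genome")) genome$circular else TRUE
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(v)
  cg <- cumsum(v == "G"); cc <- cumsum(v == "C"); ca <- cumsum(v %in% c("A", "T"))
  span_count <- function(cum, a, b) {  # 0-based half-open [a, b), b may wrap
    if (b <= L) return(cum[b] - if (a > 0) cum[a] else 0)
    (cum[L] - if (a > 0) cum[a] else 0) + cum[b - L]
  }
  starts <- seq(0L, L - 1L, by = step)
  if (!circular) starts <- starts[starts < L]
  n_g <- n_c <- n_at <- numeric(length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]
    b <- if (circular) a + window_len else min(a + window_len, L)
    n_g[i] <- span_count(cg, a, b)
    n_c[i] <- span_count(cc, a, b)
    n_at[i] <- span_count(ca, a, b)
  }
  denom <- n_g + n_c + n_at
  gc <- ifelse(denom > 0, (n_g + n_c) / denom, NA_real_)
  skew <- ifelse(n_g + n_c > 0, (n_g - n_c) / (n_g + n_c), NA_real_)
  skew0 <- ifelse(is.na(skew), 0, skew)
  structure(list(
    windows = data.frame(start = starts, gc = gc, skew = skew,
                         gc_defined = denom > 0),
    cumulative_skew = c(0, cumsum(skew0)),
    window_len = as.integer(window_len), step = as.integer(step),
    genome_length = L, circular = circular,
    mean_gc = (cg[L] + cc[L]) / (cg[L] + cc[L] + ca[L])),
    class = "window_track")
}

#' Global extrema of the cumulative GC-skew curve
#'
#' The cumulative curve starts at 0 at coordinate 0 and gains one point per
#' window; its maximum and minimum mark the putative replication
#' terminus/origin region. Ties are broken toward the smallest coordinate.
#'
#' @param track A [gc_windows()] track.
#' @return List `max_pos` and `min_pos` (bp coordinate at the end of the
#'   extremal window) and the corresponding cumulative values.
#' @export
cumulative_skew_extrema <- function(track) {
  if (all(!track$windows$gc_defined)) stop("track has no defined windows")
  cs <- track$cumulative_skew
  pos <- c(0L, track$windows$start + track$window_len)
  imax <- which.max(cs); imin <- which.min(cs)   # which.* take the first tie
  list(max_pos = min(pos[imax], track$genome_length),
       min_pos = min(pos[imin], track$genome_length),
       max_value = cs[imax], min_value = cs[imin])
}

low_gc_windows <- function(track, threshold_sd = 1.0) {
  w <- track$windows
  ok <- w$gc_defined
  thr <- mean(w$gc[ok]) - threshold_sd * sd(w$gc[ok])
  w$start[ok & w$gc < thr]
}

in_windows <- function(mids, starts, window_len, L) {
  if (length(starts) == 0L) return(rep(FALSE, length(mids)))
  hit <- rep(FALSE, length(mids))
  for (a in starts) {
    b <- a + window_len
    hit <- hit | (mids >= a & mids < b) | (b > L & mids < b - L)
  }
  hit
}

#' Association between low-GC windows and recently acquired genes
#'
#' Low-GC windows are those more than `threshold_sd` standard deviations below
#' the mean window GC. The observed statistic is the fraction of recently
#' acquired gene midpoints falling in a low-GC window. Its null distribution
#' comes from rotating all gene coordinates around the circular chromosome by
#' a uniform random offset (preserving gene spacing and clustering); the
#' p-value uses the add-one estimator p = (1 + #(null >= observed)) /
#' (1 + n_perm), which never returns 0. An independent uniform re-placement
#' null is available with `null = "shuffle"`.
#'
#' @param track A [gc_windows()] track of the same genome.
#' @param genes data.frame with `start`, `end` (0-based half-open) and
#'   `status`; rows with status in `recent_status` are the test set.
#' @param threshold_sd Low-GC threshold in SD units below the mean.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param null `"rotation"` (circular shift, default) or `"shuffle"`.
#' @param recent_status Status labels counted as recent acquisitions.
#' @return List: `observed` (fraction in low-GC windows), `p_value`,
#'   `n_recent`, `n_low_windows`, `defined` (FALSE when there are no recent
#'   genes, in which case the test is reported undefined).
#' @export
low_gc_hgt_association <- function(track, genes, threshold_sd = 1.0,
                                   n_perm = 1000L, seed = 1L,
                                   null = c("rotation", "shuffle"),
                                   recent_status = c("acquired_recent",
                                                     "hgt_recent")) {
  null <- match.arg(null)
  L <- track$genome_length
  low <- low_gc_windows(track, threshold_sd)
  rec <- genes$status %in% recent_status
  if (!any(rec))
    return(list(observed = NA_real_, p_value = NA_real_, n_recent = 0L,
                n_low_windows = length(low), defined = FALSE))
  mids <- ((genes$start + genes$end) %/% 2L) %% L
  stat <- function(m) mean(in_windows(m, low, track$window_len, L))
  observed <- stat(mids[rec])
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(b) {
    m <- if (null == "rotation") (mids + sample.int(L, 1L)) %% L
         else sample.int(L, length(mids)) - 1L
    stat(m[rec])
  }, 0)
  p <- (1 + sum(null_stats >= observed)) / (1 + n_perm)
  list(observed = observed, p_value = p, n_recent = sum(rec),
       n_low_windows = length(low), defined = TRUE)
}
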