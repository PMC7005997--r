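#' Split a genome into consecutive non-overlapping fragments
#'
#' @param genome A [genome()] object or plain DNA string.
#' @param fragment_len Fragment length in bp.
#' @return Character vector of fragments with a `starts` attribute (0-based);
#'   the trailing remainder shorter than `fragment_len` is discarded. A genome
#'   shorter than one fragment yields zero fragments with a warning.
#' @export
fragment_genome <- function(genome, fragment_len = 3000L) {
  s <- if (inherits(genome, "genome")) genome$sequence else toupper(genome)
  n_frag <- nchar(s) %/% fragment_len
  if (n_frag == 0L) {
    warning(sprintf("genome shorter than one fragment (%d < %d bp): no fragments",
                    nchar(s), fragment_len))
    return(structure(character(0), starts = integer(0)))
  }
  starts <- (seq_len(n_frag) - 1L) * fragment_len
  structure(substring(s, starts + 1L, starts + fragment_len), starts = starts)
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  km[!grepl("N", km, fixed = TRUE)]
}

#' Build a two-strand k-mer index of a reference genome
#'
#' @param ref A [genome()] or DNA string.
#' @param k k-mer size.
#' @return An object of class `ref_index` used by
#'   [estimate_fragment_identity()]; records every k-mer position on the
#'   forward strand and on the reverse complement.
#' @export
build_ref_index <- function(ref, k = 16L) {
  s <- if (inherits(ref, "genome")) ref$sequence else toupper(ref)
  rc <- reverse_complement(s)
  mk <- function(seqs, strand) {
    n <- nchar(seqs)
    km <- substring(seqs, 1:(n - k + 1L), k:n)
    keep <- !grepl("N", km, fixed = TRUE)
    data.table::data.table(kmer = km[keep], pos = which(keep) - 1L,
                           strand = strand)
  }
  idx <- data.table::rbindlist(list(mk(s, "+"), mk(rc, "-")))
  data.table::setkey(idx, kmer)
  structure(list(idx = idx, fwd = s, rev = rc, k = as.integer(k),
                 ref_len = nchar(s)), class = "ref_index")
}

#' Place one fragment on a reference and estimate its nucleotide identity
#'
#' Shared k-mers between the fragment and the indexed reference vote for a
#' diagonal (reference position minus fragment offset) on each strand; the
#' modal diagonal defines the candidate reference window. Identity is then
#' estimated from the Jaccard index j between the fragment's and the candidate
#' window's k-mer sets through the Mash relation
#' identity = 1 + (1/k) ln(2j / (1 + j)).
#'
#' @param fragment DNA string (one fragment).
#' @param ref_index A [build_ref_index()] object.
#' @param min_identity Identity floor in percent; weaker placements are
#'   reported as unmapped.
#' @param max_n_frac Fragments with more than this fraction of Ns are skipped.
#' @return A list (identity, ref_start, strand, jaccard, ref_window) or `NULL`
#'   when the fragment cannot be placed.
#' @export
estimate_fragment_identity <- function(fragment, ref_index, min_identity = 80,
                                       max_n_frac = 0.10) {
  k <- ref_index$k
  W <- nchar(fragment)
  if (W < k) return(NULL)
  n_count <- nchar(gsub("[^N]", "", fragment))
  if (n_count > max_n_frac * W) return(NULL)
  qk <- kmer_set(fragment, k)
  if (length(qk) == 0L) return(NULL)
  quniq <- unique(qk)
  hits <- ref_index$idx[data.table::data.table(kmer = quniq), nomatch = NULL,
                        on = "kmer"]
  if (nrow(hits) == 0L) return(NULL)
  qoff <- match(hits$kmer, qk) - 1L   # first occurrence offset in the fragment
  diag <- hits$pos - qoff
  key <- paste(hits$strand, diag)
  mode_key <- names(which.max(table(key)))
  parts <- strsplit(mode_key, " ", fixed = TRUE)[[1]]
  strand <- parts[1]; start <- as.integer(parts[2])
  seq_used <- if (strand == "+") ref_index$fwd else ref_index$rev
  start <- max(0L, min(start, nchar(seq_used) - W))
  window <- substr(seq_used, start + 1L, start + W)
  wk <- unique(kmer_set(window, k))
  j <- length(intersect(quniq, wk)) / length(union(quniq, wk))
  if (j <= 0) return(NULL)
  identity <- 100 * (1 + log(2 * j / (1 + j)) / k)
  if (identity < min_identity) return(NULL)
  # reference window key in forward coordinates (for reciprocal filtering)
  fwd_start <- if (strand == "+") start else ref_index$ref_len - (start + W)
  list(identity = identity, ref_start = fwd_start, strand = strand,
       jaccard = j, ref_window = fwd_start %/% W)
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' The query is cut into consecutive `fragment_len` windows; each fragment is
#' placed on the reference by shared-k-mer voting and scored by Mash-Jaccard
#' identity. Mappings are made reciprocally consistent — each reference window
#' is used by at most one fragment, ties resolved by higher Jaccard then lower
#' query coordinate — and ANI is the mean identity over the surviving
#' mappings. Mapped fraction is the proportion of query fragments that found a
#' placement; `same_species_call` applies the conventional 95% cutoff.
#'
#' @param query,ref [genome()] objects (or DNA strings).
#' @param fragment_len Fragment length (bp).
#' @param k k-mer size.
#' @param min_identity Identity floor (percent) below which a fragment counts
#'   as unmapped.
#' @param species_cutoff ANI percent at or above which the pair is called the
#'   same species.
#' @return An `ani_result` list: query_id, ref_id, ani_percent (NA when
#'   nothing maps), fragments_total, fragments_mapped, mapped_fraction,
#'   same_species_call.
#' @export
compute_ani <- function(query, ref, fragment_len = 3000L, k = 16L,
                        min_identity = 80, species_cutoff = 95) {
  qid <- if (inherits(query, "genome")) query$genome_id else "query"
  rid <- if (inherits(ref, "genome")) ref$genome_id else "ref"
  frags <- fragment_genome(query, fragment_len)
  total <- length(frags)
  idx <- build_ref_index(ref, k)
  maps <- vector("list", total)
  for (i in seq_len(total)) {
    m <- estimate_fragment_identity(frags[i], idx, min_identity)
    if (!is.null(m)) maps[[i]] <- c(m, q_start = attr(frags, "starts")[i])
  }
  maps <- maps[!vapply(maps, is.null, TRUE)]
  kept <- list()
  if (length(maps)) {
    o <- order(-vapply(maps, `[[`, 0, "jaccard"),
               vapply(maps, `[[`, 0, "q_start"))
    used <- character(0)
    for (m in maps[o]) {
      wkey <- as.character(m$ref_window)
      if (!wkey %in% used) { used <- c(used, wkey); kept[[length(kept) + 1L]] <- m }
    }
  }
  mapped <- length(kept)
  ani <- if (mapped) mean(vapply(kept, `[[`, 0, "identity")) else NA_real_
  structure(list(query_id = qid, ref_id = rid, ani_percent = ani,
                 fragments_total = total, fragments_mapped = mapped,
                 mapped_fraction = if (total) mapped / total else 0,
                 same_species_call = isTRUE(ani >= species_cutoff)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %s%% (%d/%d fragments mapped, %.3f), %s\n",
              x$query_id, x$ref_id,
              if (is.na(x$ani_percent)) "NA" else sprintf("%.1f", x$ani_percent),
              x$fragments_mapped, x$fragments_total, x$mapped_fraction,
              if (x$same_species_call) "same species (>= cutoff)"
              else "below species cutoff"))
  invisible(x)
}

#' All-vs-all ANI matrix over a set of genomes
#'
#' @param genomes Named list of [genome()] objects.
#' @param ... Passed to [compute_ani()].
#' @return data.frame with one row per ordered pair: query, ref, ani,
#'   fragments_mapped, fragments_total, mapped_fraction, same_species_call.
#' @export
ani_matrix <- function(genomes, ...) {
  ids <- vapply(genomes, `[[`, "", "genome_id")
  rows <- list()
  for (qi in seq_along(genomes)) for (ri in seq_along(genomes)) {
    if (qi == ri) next
    r <- compute_ani(genomes[[qi]], genomes[[ri]], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      query = ids[qi], ref = ids[ri], ani = r$ani_percent,
      fragments_mapped = r$fragments_mapped,
      fragments_total = r$fragments_total,
      mapped_fraction = r$mapped_fraction,
      same_species_call = r$same_species_call, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
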