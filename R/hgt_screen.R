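#' Filter homology hits by coverage and similarity
#'
#' Retains hits whose high-scoring pairs cover at least `min_query_cov` of the
#' query length AND whose overall amino-acid similarity is at least
#' `min_similarity` percent, so that retained hits represent likely full-length
#' homologs rather than genes sharing only a conserved domain. Hits whose
#' subject comes from the query's own genome are removed first (otherwise
#' every gene's best hit is itself); ranks are then recomputed per query by
#' descending bitscore, ties broken by subject_id.
#'
#' @param hits Hit table as produced by [simulate_hit_table()] or read from a
#'   tabular BLAST export with taxonomy columns.
#' @param min_query_cov Minimum fraction of the query covered by HSPs
#'   (inclusive).
#' @param min_similarity Minimum percent similarity (positives; inclusive).
#' @return The retained hits, re-ranked, same columns.
#' @export
filter_hits <- function(hits, min_query_cov = 0.90, min_similarity = 40) {
  stopifnot(all(c("query_gene", "hsp_query_cov", "percent_similarity",
                  "bitscore", "subject_id") %in% names(hits)))
  if (!is.null(hits$subject_genome) && !is.null(hits$query_genome)) {
    self <- !is.na(hits$subject_genome) & hits$subject_genome == hits$query_genome
    hits <- hits[!self, , drop = FALSE]
  }
  keep <- hits$hsp_query_cov >= min_query_cov &
    hits$percent_similarity >= min_similarity
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits)) {
    o <- order(hits$query_gene, -hits$bitscore, hits$subject_id)
    hits <- hits[o, , drop = FALSE]
    hits$rank <- as.integer(stats::ave(seq_len(nrow(hits)), hits$query_gene,
                                       FUN = seq_along))
    rownames(hits) <- NULL
  }
  hits
}

classify_one <- function(h, self_genus, top_n) {
  if (nrow(h) == 0L)
    return(list(status = "no_homologs", n_retained_hits = 0L,
                n_top5_other_genus = 0L, best_hit_genus = NA_character_,
                donor_genus = NA_character_, donor_order = NA_character_,
                donor_phylum = NA_character_))
  h <- h[order(h$rank), , drop = FALSE]
  top <- h[seq_len(min(top_n, nrow(h))), , drop = FALSE]
  best <- top[1L, ]
  if (is.na(best$subject_genus) || isTRUE(best$metagenomic_flag)) {
    status <- "ambiguous_taxonomy"
    donor <- best
  } else {
    other <- is.na(top$subject_genus) | top$subject_genus != self_genus
    acquired <- sum(other) * 2L > nrow(top)   # strictly more than half
    if (!acquired) {
      status <- "native"; donor <- NULL
    } else {
      recent <- best$subject_genus != self_genus
      status <- if (recent) "acquired_recent" else "acquired_other"
      nonself <- top[other, , drop = FALSE]
      donor <- nonself[1L, ]  # best-ranked non-self hit
    }
  }
  list(status = status, n_retained_hits = nrow(h),
       n_top5_other_genus = sum(is.na(top$subject_genus) |
                                  top$subject_genus != self_genus),
       best_hit_genus = best$subject_genus,
       donor_genus = if (is.null(donor)) NA_character_ else donor$subject_genus,
       donor_order = if (is.null(donor)) NA_character_ else donor$subject_order,
       donor_phylum = if (is.null(donor)) NA_character_ else donor$subject_phylum)
}

#' Classify genes as native or horizontally acquired by taxonomic voting
#'
#' Applies [filter_hits()], then votes over the top `top_n` retained hits of
#' each gene: a gene is putatively acquired when strictly more than half of
#' those hits come from genera other than `self_genus`; among acquired genes,
#' those whose single best hit is from another genus are called recent
#' acquisitions (transfer after the genus diverged), the rest older ones. A
#' best hit without genus-level taxonomy or flagged as metagenomic sends the
#' gene to the `ambiguous_taxonomy` bucket for manual examination; genes with
#' no retained hits are `no_homologs`. With fewer than `top_n` retained hits
#' the same strict-majority rule is applied to the hits available.
#'
#' @param hits Raw hit table (filtering is applied internally).
#' @param self_genus Genus of the query genome.
#' @param top_n Number of top hits voting (default five).
#' @param min_query_cov,min_similarity Passed to [filter_hits()].
#' @param genes Optional character vector of all query locus_tags; genes
#'   absent from `hits` are reported as `no_homologs`.
#' @return data.frame with one row per gene: gene_id, status,
#'   n_retained_hits, n_top5_other_genus, best_hit_genus, donor_genus,
#'   donor_order, donor_phylum.
#' @export
classify_genes <- function(hits, self_genus, top_n = 5L,
                           min_query_cov = 0.90, min_similarity = 40,
                           genes = NULL) {
  retained <- filter_hits(hits, min_query_cov, min_similarity)
  ids <- unique(c(if (!is.null(genes)) as.character(genes),
                  unique(hits$query_gene)))
  grp <- if (nrow(retained)) split(seq_len(nrow(retained)),
                                   retained$query_gene) else list()
  calls <- lapply(ids, function(g) {
    h <- if (g %in% names(grp)) retained[grp[[g]], , drop = FALSE] else
      retained[0L, , drop = FALSE]
    c(list(gene_id = g), classify_one(h, self_genus, top_n))
  })
  out <- do.call(rbind, lapply(calls, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Summarize putative donors of recent acquisitions by taxonomic group
#'
#' Recent acquisitions are grouped by the taxonomy of the best non-self hit:
#' same order as the self genome ("self_order"), other Cyanobacteria, the
#' phylum Proteobacteria, and everything else.
#'
#' @param calls Output of [classify_genes()].
#' @param self_order Order of the self genome (donors in it form one group).
#' @param cyano_phylum Phylum label treated as "other Cyanobacteria".
#' @return data.frame(group, count, fraction); fractions sum to 1 over calls
#'   with a donor label. Zero recent calls give zero counts.
#' @export
summarize_donors <- function(calls, self_order = "Synechococcales",
                             cyano_phylum = "Cyanobacteria") {
  rec <- calls[calls$status == "acquired_recent" & !is.na(calls$donor_genus), ,
               drop = FALSE]
  groups <- c("self_order", "other_cyanobacteria", "Proteobacteria", "other")
  grp <- with(rec, ifelse(donor_order == self_order, "self_order",
                   ifelse(donor_phylum == cyano_phylum, "other_cyanobacteria",
                   ifelse(donor_phylum == "Proteobacteria", "Proteobacteria",
                          "other"))))
  counts <- table(factor(grp, levels = groups))
  data.frame(group = groups, count = as.integer(counts),
             fraction = if (sum(counts) > 0) as.numeric(counts / sum(counts))
                        else rep(NA_real_, length(groups)),
             stringsAsFactors = FALSE)
}

#' Tally functional categories (COG letters) of a set of gene calls
#'
#' Counts genes per COG letter. Multi-letter assignments (e.g. "EP") count
#' once per letter, so per-letter counts can exceed the gene total; a total
#' under the count-once-per-gene convention is returned alongside. Genes
#' without an assignment go to the "unassigned" bucket.
#'
#' @param calls Output of [classify_genes()] (any subset, e.g. recent calls).
#' @param annotations A [gene_table()] (or row-bound tables across genomes)
#'   carrying `locus_tag` and `cog_category`.
#' @return List with `per_letter` (data.frame cog, count), `n_genes`,
#'   `n_assigned`, `n_unassigned`.
#' @export
summarize_functions <- function(calls, annotations) {
  miss <- setdiff(calls$gene_id, annotations$locus_tag)
  if (length(miss))
    stop(sprintf("gene '%s' in calls is missing from annotations", miss[1]))
  cog <- annotations$cog_category[match(calls$gene_id, annotations$locus_tag)]
  assigned <- !is.na(cog) & nzchar(cog)
  letters <- unlist(strsplit(cog[assigned], ""))
  tab <- sort(table(letters), decreasing = TRUE)
  per_letter <- data.frame(cog = c(names(tab), "unassigned"),
                           count = c(as.integer(tab), sum(!assigned)),
                           stringsAsFactors = FALSE)
  list(per_letter = per_letter, n_genes = nrow(calls),
       n_assigned = sum(assigned), n_unassigned = sum(!assigned))
}
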