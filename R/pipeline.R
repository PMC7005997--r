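#' Assemble a pipeline configuration
#'
#' Exactly one of `simulator` (a [clade_config()]) or `paths` (real inputs:
#' named list with `fasta`, `gff`, `hits`, `tree`, `outgroup`) must be given.
#' Stage parameters not supplied are materialized from the package defaults so
#' the emitted config copy records every value actually used.
#'
#' @param out_dir Output directory (created if missing).
#' @param simulator Optional [clade_config()].
#' @param paths Optional list of real input paths.
#' @param seed Integer seed for every stochastic stage.
#' @param self_genus,self_order Taxonomy of the focal clade for the transfer
#'   screen.
#' @param ani,hgt,landscape,synteny,tree Named lists overriding stage
#'   defaults (see the respective functions).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulator = NULL, paths = NULL, seed = 1L,
                            self_genus = "Thermosynechococcus",
                            self_order = "Synechococcales",
                            ani = list(), hgt = list(), landscape = list(),
                            synteny = list(), tree = list()) {
  if (is.null(simulator) == is.null(paths))
    stop("exactly one of 'simulator' or 'paths' must be set")
  defaults <- list(
    ani = list(fragment_len = 3000L, k = 16L, min_identity = 80,
               species_cutoff = 95),
    hgt = list(min_query_cov = 0.90, min_similarity = 40, top_n = 5L),
    landscape = list(window_len = 10000L, threshold_sd = 1.0,
                     n_perm = 1000L),
    synteny = list(min_match_len = 20L, min_cluster_len = 200L,
                   max_gap = 500L, margin = 2000L, n_perm = 1000L),
    tree = list(n_bootstrap = 200L))
  merge1 <- function(d, o) { d[names(o)] <- o; d }
  structure(list(out_dir = out_dir, simulator = simulator, paths = paths,
                 seed = as.integer(seed), self_genus = self_genus,
                 self_order = self_order,
                 ani = merge1(defaults$ani, ani),
                 hgt = merge1(defaults$hgt, hgt),
                 landscape = merge1(defaults$landscape, landscape),
                 synteny = merge1(defaults$synteny, synteny),
                 tree = merge1(defaults$tree, tree)),
            class = "pipeline_config")
}

tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative-genomics pipeline
#'
#' Simulator mode: generates the clade, then runs every analysis stage — ANI
#' matrix, ortholog clustering with phyletic accounting and the core-genome
#' distance tree, the transfer screen with donor and functional summaries
#' (scored against simulated truth), the GC landscape with the low-GC
#' association test, and synteny anchoring with breakpoint/mobilome
#' correspondence — writing plain-text outputs (TSV/BED/Newick/FASTA/GFF3) and
#' a JSON run manifest into `config$out_dir`. Real-input mode runs the same
#' stages on user files and skips truth-based scoring. Deterministic given
#' `config$seed`; a stage failure halts the run with the stage named and
#' leaves a `FAILED` marker alongside any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("cladescope")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 out("FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- inputs ----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulator)) {
    sim <- stage("simulate", simulate_clade(config$simulator))
    genomes <- sim$genomes; truth <- sim$truth; proteins <- sim$proteins
    species_tree <- sim$tree
    outgroup <- config$simulator$outgroup
    taxonomy <- clade_taxonomy(names(genomes), self_genus = config$self_genus,
                               self_order = config$self_order)
    hits <- stage("simulate_hits",
                  simulate_hit_table(truth$genes, taxonomy,
                                     self_genus = config$self_genus,
                                     seed = config$seed))
    for (g in genomes) {
      write_fasta(g, out(paste0(g$genome_id, ".fa")))
      write_gff3(g, out(paste0(g$genome_id, ".gff3")))
    }
    ape::write.tree(species_tree, out("true_tree.nwk"))
    tsv(truth$genes, out("truth_genes.tsv"))
    tsv(truth$events, out("truth_events.tsv"))
    tsv(hits, out("hits.tsv"))
  } else {
    p <- config$paths
    genomes <- stage("read_inputs", {
      gs <- unlist(lapply(p$fasta, read_fasta), recursive = FALSE)
      if (!is.null(p$gff))
        gs <- lapply(seq_along(gs), function(i) read_gff3(p$gff[[i]], gs[[i]]))
      setNames(gs, vapply(gs, `[[`, "", "genome_id"))
    })
    hits <- stage("read_inputs", read.table(p$hits, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE))
    species_tree <- if (!is.null(p$tree)) ape::read.tree(p$tree) else NULL
    outgroup <- p$outgroup
    proteins <- NULL
  }

  # --- ANI -------------------------------------------------------------------
  ani <- stage("ani", do.call(ani_matrix, c(list(genomes), config$ani)))
  tsv(ani, out("ani_matrix.tsv"))
  manifest$ani <- list(n_pairs = nrow(ani),
                       min_ani = suppressWarnings(min(ani$ani, na.rm = TRUE)))

  # --- pangenome -------------------------------------------------------------
  if (!is.null(proteins)) {
    clusters <- stage("orthologs", cluster_orthologs(proteins))
    tsv(clusters$membership, out("cluster_membership.tsv"))
    pm <- data.frame(cluster = rownames(clusters$phyletic_matrix),
                     clusters$phyletic_matrix, check.names = FALSE)
    tsv(pm, out("phyletic_matrix.tsv"))
    core <- core_and_single_copy(clusters)
    uniq <- unique_per_genome(clusters)
    tsv(data.frame(genome_id = names(uniq), unique_clusters = as.integer(uniq)),
        out("unique_clusters.tsv"))
    nj <- stage("tree", {
      sm <- concatenate_core(clusters, proteins)
      distance_tree(sm, outgroup = outgroup,
                    n_bootstrap = config$tree$n_bootstrap, seed = config$seed)
    })
    ape::write.tree(nj$tree, out("core_genome_tree.nwk"))
    ref_tree <- if (!is.null(species_tree)) species_tree else nj$tree
    bc <- stage("branch_counts", branch_unique_counts(ref_tree, clusters))
    tsv(bc, out("branch_unique_counts.tsv"))
    manifest$pangenome <- list(n_clusters = nrow(clusters$phyletic_matrix),
                               n_core = length(core$core),
                               n_single_copy_core = length(core$single_copy_core),
                               min_bootstrap = min(nj$support))
  }

  # --- transfer screen -------------------------------------------------------
  all_ann <- do.call(rbind, lapply(genomes, function(g) g$annotations))
  cds_ids <- all_ann$locus_tag[all_ann$feature_kind == "CDS"]
  calls <- stage("hgt_screen",
                 classify_genes(hits, self_genus = config$self_genus,
                                top_n = config$hgt$top_n,
                                min_query_cov = config$hgt$min_query_cov,
                                min_similarity = config$hgt$min_similarity,
                                genes = intersect(cds_ids,
                                                  unique(hits$query_gene))))
  tsv(calls, out("hgt_calls.tsv"))
  donors <- summarize_donors(calls, self_order = config$self_order)
  tsv(donors, out("hgt_donor_summary.tsv"))
  fun <- summarize_functions(calls[calls$status == "acquired_recent", ,
                                   drop = FALSE], all_ann)
  tsv(fun$per_letter, out("hgt_function_summary.tsv"))
  manifest$hgt <- list(n_genes = nrow(calls),
                       n_acquired = sum(calls$status %in%
                                          c("acquired_recent", "acquired_other")),
                       n_recent = sum(calls$status == "acquired_recent"))
  if (!is.null(truth)) {
    sc <- hgt_recovery_score(calls, truth$genes)
    manifest$hgt$precision <- sc$precision
    manifest$hgt$recall <- sc$recall
  }

  # --- GC landscape (focal genome = first) -----------------------------------
  focal <- genomes[[1L]]
  track <- stage("landscape", gc_windows(focal,
                                         window_len = config$landscape$window_len))
  tsv(track$windows, out(paste0(focal$genome_id, "_gc_windows.tsv")))
  ext <- cumulative_skew_extrema(track)
  low <- low_gc_windows(track, config$landscape$threshold_sd)
  if (length(low))
    tsv(data.frame(chrom = focal$genome_id, start = low,
                   end = pmin(low + track$window_len, track$genome_length)),
        out(paste0(focal$genome_id, "_low_gc.bed")))
  gene_status <- merge(focal$annotations,
                       calls[, c("gene_id", "status")],
                       by.x = "locus_tag", by.y = "gene_id", all.x = TRUE)
  assoc <- stage("landscape",
                 low_gc_hgt_association(track, gene_status,
                                        threshold_sd = config$landscape$threshold_sd,
                                        n_perm = config$landscape$n_perm,
                                        seed = config$seed))
  manifest$landscape <- list(genome = focal$genome_id,
                             mean_gc = track$mean_gc,
                             skew_max_pos = ext$max_pos,
                             low_gc_assoc_observed = assoc$observed,
                             low_gc_assoc_p = assoc$p_value)

  # --- synteny: focal pair = the two genomes richest in mobile elements, so
  # the breakpoint/mobilome correspondence is informative; ties keep input order
  if (length(genomes) >= 2L) {
    n_mob <- vapply(genomes, function(g)
      sum(g$annotations$feature_kind == "mobile_element"), 0L)
    ord <- order(-n_mob, seq_along(genomes))
    q <- genomes[[ord[1L]]]; r <- genomes[[ord[2L]]]
    anchors <- stage("synteny",
                     find_anchors(q, r, config$synteny$min_match_len))
    tsv(anchors, out(sprintf("anchors_%s_%s.tsv", q$genome_id, r$genome_id)))
    blocks <- cluster_anchors(anchors, config$synteny$min_cluster_len,
                              config$synteny$max_gap)
    tsv(blocks, out(sprintf("blocks_%s_%s.tsv", q$genome_id, r$genome_id)))
    bps <- breakpoints(blocks, nchar(q$sequence))
    tsv(bps, out(sprintf("breakpoints_%s_%s.tsv", q$genome_id, r$genome_id)))
    mob <- q$annotations[q$annotations$feature_kind == "mobile_element", ,
                         drop = FALSE]
    ov <- mobilome_breakpoint_overlap(bps, mob, nchar(q$sequence),
                                      margin = config$synteny$margin,
                                      n_perm = config$synteny$n_perm,
                                      seed = config$seed)
    manifest$synteny <- list(pair = c(q$genome_id, r$genome_id),
                             n_anchors = nrow(anchors),
                             n_blocks = nrow(blocks),
                             n_breakpoints = nrow(bps),
                             mobilome_overlap = ov$observed,
                             mobilome_overlap_p = ov$p_value)
  }

  # --- manifest --------------------------------------------------------------
  cfg_path <- out("config_used.yaml")
  yaml::write_yaml(config_as_list(config), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL   # environmental, not part of the analysis identity
  if (!is.null(x$simulator)) {
    s <- unclass(x$simulator)
    s$tree <- ape::write.tree(s$tree)
    s$donor_pool <- as.list(s$donor_pool)
    s$is_element$copies <- as.list(s$is_element$copies)
    s$n_inversions <- as.list(s$n_inversions)
    x$simulator <- s
  }
  x
}

#' Score transfer calls against simulated truth
#'
#' Maps truth statuses to classifier statuses (native to native, recent
#' transfer to `acquired_recent`, ancestral transfer to `acquired_other`) and
#' reports exact-match precision and recall of the acquired classes plus the
#' per-class confusion table.
#'
#' @param calls Output of [classify_genes()].
#' @param truth_genes `truth$genes` from [simulate_clade()].
#' @return List: precision, recall, accuracy, confusion (table).
#' @export
hgt_recovery_score <- function(calls, truth_genes) {
  map <- c(native = "native", hgt_recent = "acquired_recent",
           hgt_ancestral = "acquired_other")
  m <- merge(calls[, c("gene_id", "status")],
             data.frame(gene_id = truth_genes$gene_id,
                        truth = unname(map[truth_genes$status]),
                        stringsAsFactors = FALSE), by = "gene_id")
  pos <- c("acquired_recent", "acquired_other")
  tp <- sum(m$status %in% pos & m$status == m$truth)
  fp <- sum(m$status %in% pos & m$status != m$truth)
  fn <- sum(m$truth %in% pos & m$status != m$truth)
  list(precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       accuracy = mean(m$status == m$truth),
       confusion = table(truth = m$truth, call = m$status))
}
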