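DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
COG_LETTERS <- strsplit("JKLDVTMNUOCGEFHIPQRS", "")[[1]]

default_clade_tree <- function() {
  paste0("(((CL1:0.04,SCTE542:0.04):0.02,((BP1:0.01,NIES2134:0.01):0.02,",
         "NK55:0.03):0.03):0.08,SLIV:0.16);")
}

#' Default genome-to-taxonomy map for the simulated clade
#'
#' One row per simulated genome: all clade members share the self genus so
#' that only transfer events introduce foreign taxa into homology-hit tables.
#'
#' @param genome_ids Character vector of genome labels.
#' @param self_genus,self_order,self_phylum Taxonomy shared by all genomes.
#' @return data.frame with columns genome_id, genus, order, phylum.
#' @export
clade_taxonomy <- function(genome_ids,
                           self_genus = "Thermosynechococcus",
                           self_order = "Synechococcales",
                           self_phylum = "Cyanobacteria") {
  data.frame(genome_id = genome_ids, genus = self_genus, order = self_order,
             phylum = self_phylum, stringsAsFactors = FALSE)
}

default_donor_pool <- function() {
  data.frame(
    genus = c("Leptolyngbya", "Nostoc", "Pseudomonas", "Bacillus"),
    order = c("Synechococcales", "Nostocales", "Pseudomonadales", "Bacillales"),
    phylum = c("Cyanobacteria", "Cyanobacteria", "Proteobacteria", "Bacillota"),
    weight = c(0.42, 0.29, 0.17, 0.12),
    stringsAsFactors = FALSE)
}

#' Configuration for the clade simulator
#'
#' Defaults describe a six-genome thermophilic cyanobacterial clade with an
#' outgroup: host GC 53.5%, donor GC 12 points below host, around five
#' transfer events expected per branch, mobile-element proliferation and
#' chromosomal inversions restricted to one sister pair. Genome size and gene
#' count are scaled down from megabase chromosomes so a full clade simulates
#' in seconds; divergence levels are not scaled.
#'
#' @param tree Newick string or `ape::phylo`, rooted, with branch lengths in
#'   substitutions/site.
#' @param outgroup Leaf label used to root downstream trees.
#' @param genome_length Ancestral chromosome length (bp).
#' @param n_gene_families Number of vertically inherited gene families.
#' @param mean_gene_len Mean gene length (bp, multiples of 3).
#' @param host_gc,donor_gc GC fractions of host genome and of acquired
#'   segments at insertion.
#' @param hgt_rate Expected transfer insertions per branch of average length
#'   (Poisson mean scales with branch length / tree height).
#' @param amelioration_rate Fractional decay of the donor-host GC offset per
#'   unit branch length after acquisition (0 = no amelioration; offsets decay
#'   linearly and clamp at full amelioration).
#' @param is_element List with `length` (bp) and `copies`, a named integer
#'   vector of insertion-sequence copy numbers per lineage.
#' @param n_inversions Named integer vector: inversions per lineage.
#' @param is_at_breakpoints Place mobile-element copies exactly at inversion
#'   boundaries (for breakpoint-association checks) instead of uniformly.
#' @param donor_pool data.frame(genus, order, phylum, weight) sampled per
#'   transfer event.
#' @param seed Integer seed; every random draw flows from it.
#' @return A `clade_config` list, validated.
#' @export
clade_config <- function(tree = default_clade_tree(),
                         outgroup = "SLIV",
                         genome_length = 150000L,
                         n_gene_families = 150L,
                         mean_gene_len = 600L,
                         host_gc = 0.535,
                         donor_gc = 0.415,
                         hgt_rate = 5,
                         amelioration_rate = 2,
                         is_element = list(length = 1200L,
                                           copies = c(BP1 = 8L, NIES2134 = 8L)),
                         n_inversions = c(BP1 = 2L, NIES2134 = 2L),
                         is_at_breakpoints = FALSE,
                         donor_pool = default_donor_pool(),
                         seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  cfg <- structure(list(tree = tree, outgroup = outgroup,
                        genome_length = as.integer(genome_length),
                        n_gene_families = as.integer(n_gene_families),
                        mean_gene_len = as.integer(mean_gene_len),
                        host_gc = host_gc, donor_gc = donor_gc,
                        hgt_rate = hgt_rate,
                        amelioration_rate = amelioration_rate,
                        is_element = is_element,
                        n_inversions = n_inversions,
                        is_at_breakpoints = isTRUE(is_at_breakpoints),
                        donor_pool = donor_pool, seed = as.integer(seed)),
                   class = "clade_config")
  validate_clade_config(cfg)
  cfg
}

validate_clade_config <- function(cfg) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid clade_config: '%s' must be a fraction in [0,1]", nm))
  }
  chk_frac(cfg$host_gc, "host_gc"); chk_frac(cfg$donor_gc, "donor_gc")
  if (!inherits(cfg$tree, "phylo") || length(cfg$tree$tip.label) < 2L)
    stop("invalid clade_config: 'tree' must be a rooted phylo with >= 2 leaves")
  if (is.null(cfg$tree$edge.length))
    stop("invalid clade_config: 'tree' must carry branch lengths")
  if (!cfg$outgroup %in% cfg$tree$tip.label)
    stop("invalid clade_config: 'outgroup' is not a leaf of 'tree'")
  if (cfg$hgt_rate < 0) stop("invalid clade_config: 'hgt_rate' must be >= 0")
  if (cfg$amelioration_rate < 0)
    stop("invalid clade_config: 'amelioration_rate' must be >= 0")
  # conservative bound: mean gene length x families must fit the chromosome
  if (cfg$genome_length < cfg$n_gene_families * cfg$mean_gene_len)
    stop("invalid clade_config: 'genome_length' smaller than total gene length")
  bad <- setdiff(c(names(cfg$n_inversions), names(cfg$is_element$copies)),
                 cfg$tree$tip.label)
  if (length(bad))
    stop(sprintf("invalid clade_config: lineage '%s' (in 'n_inversions'/'is_element') is not a leaf",
                 bad[1]))
  invisible(cfg)
}

rand_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Jukes-Cantor: substitute each site with prob 3/4 (1 - e^{-4t/3}),
# replacement uniform over the three other bases; N sites untouched.
mutate_dna <- function(v, t) {
  p <- 0.75 * (1 - exp(-4 * t / 3))
  idx <- which(runif(length(v)) < p)
  if (length(idx)) {
    m <- match(v[idx], DNA_BASES)
    ok <- which(!is.na(m))
    if (length(ok)) {
      r <- sample.int(3L, length(ok), replace = TRUE)
      v[idx[ok]] <- DNA_BASES[((m[ok] - 1L + r) %% 4L) + 1L]
    }
  }
  v
}

# Poisson model on amino acids: per-site substitution prob 1 - e^{-t}.
mutate_protein <- function(s, t) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  p <- 1 - exp(-t)
  idx <- which(runif(length(v)) < p)
  if (length(idx)) {
    m <- match(v[idx], AA_ALPHABET)
    r <- sample.int(19L, length(idx), replace = TRUE)
    v[idx] <- AA_ALPHABET[((m - 1L + r) %% 20L) + 1L]
  }
  paste(v, collapse = "")
}

# Resample each site's GC/AT category independently with P(GC) = target,
# keeping the existing base where the category is unchanged. Per-site
# independence gives the segment the same binomial composition variance as
# host background drawn at the same GC, so fully ameliorated segments are
# compositionally exchangeable with native sequence.
adjust_gc <- function(v, target) {
  want_gc <- runif(length(v)) < target
  is_gc <- v %in% c("G", "C")
  to_gc <- which(want_gc & !is_gc)
  to_at <- which(!want_gc & is_gc)
  v[to_gc] <- sample(c("G", "C"), length(to_gc), replace = TRUE)
  v[to_at] <- sample(c("A", "T"), length(to_at), replace = TRUE)
  v
}

# Insertion point chosen uniformly among intergenic gaps (midpoint used);
# returns the updated state with all downstream coordinates shifted.
splice_segment <- function(state, seg, row) {
  gaps <- intergenic_points(state$genes, length(state$seq))
  pos <- gaps[sample.int(length(gaps), 1L)]
  insert_at(state, seg, row, pos)
}

insert_at <- function(state, seg, row, pos) {
  n <- length(seg)
  state$seq <- c(state$seq[seq_len(pos)], seg,
                 if (pos < length(state$seq))
                   state$seq[(pos + 1L):length(state$seq)])
  g <- state$genes
  shift <- g$start >= pos
  g$start[shift] <- g$start[shift] + n
  g$end[shift] <- g$end[shift] + n
  row$start <- pos; row$end <- pos + n
  state$genes <- rbind(g, row)
  state
}

intergenic_points <- function(genes, len) {
  g <- genes[order(genes$start), , drop = FALSE]
  lo <- c(0L, g$end)
  hi <- c(g$start, len)
  mid <- as.integer(floor((lo + hi) / 2))
  mid[hi > lo]
}

new_gene_row <- function(family, start, end, strand, kind, status,
                         event_id = NA_character_, insert_depth = NA_real_,
                         cog = NA_character_, product = NA_character_) {
  data.frame(family = family, start = as.integer(start), end = as.integer(end),
             strand = strand, kind = kind, status = status,
             event_id = event_id, insert_depth = insert_depth, cog = cog,
             product = product, residual_gc_offset = 0,
             stringsAsFactors = FALSE)
}

sample_cog <- function(n, hgt = FALSE) {
  if (hgt) {
    # recent acquisitions are mostly functionally unassigned, with transport
    # and metabolism categories dominating the assigned remainder
    pool <- c(NA, "P", "E", COG_LETTERS)
    prob <- c(0.72, 0.10, 0.07, rep(0.11 / length(COG_LETTERS),
                                    length(COG_LETTERS)))
  } else {
    pool <- c(NA, COG_LETTERS)
    prob <- c(0.25, rep(0.75 / length(COG_LETTERS), length(COG_LETTERS)))
  }
  sample(pool, n, replace = TRUE, prob = prob)
}

#' Simulate an annotated clade with truth-labelled horizontal transfers
#'
#' Evolves an ancestral chromosome down the configured tree under a
#' Jukes-Cantor single-nucleotide substitution process, inserts horizontal
#' acquisitions (Poisson per branch, mean proportional to branch length) as
#' contiguous donor-GC segments that ameliorate linearly toward host GC,
#' proliferates an insertion sequence and applies chromosomal inversions in
#' the named lineages, and evolves indel-free protein families (Poisson amino
#' acid model) for clustering and phylogeny. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [clade_config()].
#' @return List with elements `genomes` (named list of [genome()] objects),
#'   `truth` (list of data.frames: `genes`, `events`, `inversions`),
#'   `proteins` (per-genome named character vectors, locus_tag to amino-acid
#'   sequence), `families` (data.frame locus_tag/genome_id/family), and
#'   `tree` (the true `phylo`).
#' @export
simulate_clade <- function(config) {
  validate_clade_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  tree <- ape::reorder.phylo(config$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])

  # --- ancestor ------------------------------------------------------------
  aa_len <- pmax(50L, round(config$mean_gene_len / 3 +
                              rnorm(config$n_gene_families,
                                    sd = config$mean_gene_len / 15)))
  gene_len <- 3L * aa_len
  if (sum(gene_len) > config$genome_length)
    stop("invalid clade_config: 'genome_length' smaller than total gene length")
  fam_ids <- sprintf("FAM%04d", seq_len(config$n_gene_families))
  fam_cog <- sample_cog(config$n_gene_families)
  anc_seq <- rand_dna(config$genome_length, config$host_gc)
  gap <- (config$genome_length - sum(gene_len)) %/% (config$n_gene_families + 1L)
  starts <- cumsum(c(gap, head(gene_len + gap, -1L)))
  genes <- new_gene_row(fam_ids, starts, starts + gene_len,
                        sample(c("+", "-"), config$n_gene_families, TRUE),
                        "CDS", "native", cog = fam_cog)
  anc_prot <- setNames(vapply(aa_len, function(l)
    paste(sample(AA_ALPHABET, l, TRUE), collapse = ""), ""), fam_ids)

  # --- evolve along the tree ----------------------------------------------
  states <- vector("list", max(tree$edge))
  states[[root]] <- list(seq = anc_seq, genes = genes, prot = anc_prot)
  events <- list(); ev_n <- 0L
  branch_label <- function(child) {
    leaves <- if (child <= ntip) tree$tip.label[child] else
      sort(ape::extract.clade(tree, child)$tip.label)
    paste(sort(leaves), collapse = "|")
  }
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
    t <- tree$edge.length[i]
    st <- states[[parent]]
    st$seq <- mutate_dna(st$seq, t)
    st$prot <- vapply(st$prot, mutate_protein, "", t = t)
    n_ev <- if (height > 0 && t > 0) rpois(1L, config$hgt_rate * t / height)
            else 0L
    for (k in seq_len(n_ev)) {
      ev_n <- ev_n + 1L
      ev_id <- sprintf("EV%04d", ev_n)
      d <- config$donor_pool[sample.int(nrow(config$donor_pool), 1L,
                                        prob = config$donor_pool$weight), ]
      l_aa <- max(50L, round(config$mean_gene_len / 3 +
                               rnorm(1L, sd = config$mean_gene_len / 15)))
      seg <- rand_dna(3L * l_aa, config$donor_gc)
      row <- new_gene_row(ev_id, 0L, 0L, sample(c("+", "-"), 1L), "CDS",
                          if (child <= ntip) "hgt_recent" else "hgt_ancestral",
                          event_id = ev_id, insert_depth = depth[parent],
                          cog = sample_cog(1L, hgt = TRUE))
      st <- splice_segment(st, seg, row)
      st$prot[[ev_id]] <- paste(sample(AA_ALPHABET, l_aa, TRUE), collapse = "")
      events[[ev_n]] <- data.frame(
        event_id = ev_id, branch = branch_label(child),
        terminal = child <= ntip, donor_genus = d$genus,
        donor_order = d$order, donor_phylum = d$phylum,
        donor_gc = config$donor_gc, length_bp = 3L * l_aa,
        insert_depth = depth[parent], stringsAsFactors = FALSE)
    }
    states[[child]] <- st
  }

  # --- leaf realization ----------------------------------------------------
  genomes <- list(); truth_genes <- list(); inversions <- list()
  proteins <- list(); families <- list()
  is_master <- rand_dna(config$is_element$length %||% 1200L, config$donor_gc)
  for (leaf in seq_len(ntip)) {
    label <- tree$tip.label[leaf]
    st <- states[[leaf]]

    # amelioration: decay of the donor-host GC offset with time since insertion.
    # The target tracks the leaf's realized background composition (the native
    # genome drifts toward 0.5 under the symmetric substitution model), so a
    # fully ameliorated segment is compositionally indistinguishable from it.
    hgt <- which(st$genes$status != "native")
    if (length(hgt)) {
      in_hgt <- rep(FALSE, length(st$seq))
      for (j in hgt) in_hgt[(st$genes$start[j] + 1L):st$genes$end[j]] <- TRUE
      bg_gc <- mean(st$seq[!in_hgt] %in% c("G", "C"))
      for (j in hgt) {
        t_since <- depth[leaf] - st$genes$insert_depth[j]
        resid <- (config$donor_gc - config$host_gc) *
          max(0, 1 - config$amelioration_rate * t_since)
        st$genes$residual_gc_offset[j] <- resid
        span <- (st$genes$start[j] + 1L):st$genes$end[j]
        st$seq[span] <- adjust_gc(st$seq[span], bg_gc + resid)
      }
    }

    # inversions between intergenic points, genes remapped, strands flipped
    n_inv <- lookup0(config$n_inversions, label)
    inv_bounds <- integer(0)
    for (k in seq_len(n_inv)) {
      pts <- intergenic_points(st$genes, length(st$seq))
      inside <- function(a, b) any(st$genes$start >= a & st$genes$end <= b)
      for (try in 1:50) {
        ab <- sort(sample(pts, 2L))
        if (ab[2] - ab[1] >= 1000L && inside(ab[1], ab[2])) break
      }
      a <- ab[1]; b <- ab[2]
      seg <- st$seq[(a + 1L):b]
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      st$seq[(a + 1L):b] <- unname(comp[rev(seg)])
      g <- st$genes
      in_seg <- g$start >= a & g$end <= b
      ns <- a + b - g$end[in_seg]; ne <- a + b - g$start[in_seg]
      g$start[in_seg] <- ns; g$end[in_seg] <- ne
      g$strand[in_seg] <- ifelse(g$strand[in_seg] == "+", "-", "+")
      st$genes <- g
      # earlier boundaries inside [a, b) move with the inverted segment
      inside_b <- inv_bounds > a & inv_bounds < b
      inv_bounds[inside_b] <- a + b - inv_bounds[inside_b]
      inv_bounds <- c(inv_bounds, a, b)
    }
    if (length(inv_bounds))
      inversions[[length(inversions) + 1L]] <-
        data.frame(genome_id = label,
                   start = sort(inv_bounds)[c(TRUE, FALSE)],
                   end = sort(inv_bounds)[c(FALSE, TRUE)],
                   stringsAsFactors = FALSE)

    # insertion-sequence proliferation
    n_is <- lookup0(config$is_element$copies, label)
    if (n_is > 0L) {
      if (config$is_at_breakpoints && length(inv_bounds)) {
        at <- rep_len(sort(inv_bounds, decreasing = TRUE), n_is)
      } else at <- NULL
      for (k in seq_len(n_is)) {
        is_seq <- mutate_dna(is_master, 0.01)
        row <- new_gene_row(sprintf("IS_%s_%02d", label, k), 0L, 0L,
                            sample(c("+", "-"), 1L), "mobile_element",
                            "native",
                            product = "transposase, insertion sequence")
        st <- if (is.null(at)) splice_segment(st, is_seq, row) else
          insert_at(st, is_seq, row, at[k])
      }
    }

    # finalize: locus tags in chromosome order
    g <- st$genes[order(st$genes$start), , drop = FALSE]
    g$locus_tag <- sprintf("%s_%05d", label, seq_len(nrow(g)) * 5L)
    if (is.null(g$product)) g$product <- NA_character_
    g$product[is.na(g$product)] <-
      ifelse(g$status[is.na(g$product)] == "native",
             "hypothetical protein", "hypothetical protein, acquired")
    ann <- gene_table(locus_tag = g$locus_tag, start = g$start, end = g$end,
                      strand = g$strand, feature_kind = g$kind,
                      product = g$product, cog_category = g$cog)
    genomes[[label]] <- genome(label, paste(st$seq, collapse = ""),
                               circular = TRUE, annotations = ann)
    cds <- g$kind == "CDS"
    truth_genes[[label]] <- data.frame(
      gene_id = g$locus_tag[cds], genome_id = label, family = g$family[cds],
      status = g$status[cds],
      event_id = g$event_id[cds],
      insertion_branch = NA_character_,
      start = g$start[cds], end = g$end[cds],
      residual_gc_offset = g$residual_gc_offset[cds],
      stringsAsFactors = FALSE)
    proteins[[label]] <- setNames(unlist(st$prot[g$family[cds]]),
                                  g$locus_tag[cds])
    families[[label]] <- data.frame(locus_tag = g$locus_tag[cds],
                                    genome_id = label, family = g$family[cds],
                                    stringsAsFactors = FALSE)
  }

  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(), branch = character(),
               terminal = logical(), donor_genus = character(),
               donor_order = character(), donor_phylum = character(),
               donor_gc = numeric(), length_bp = integer(),
               insert_depth = numeric(), stringsAsFactors = FALSE)
  genes_df <- do.call(rbind, truth_genes)
  rownames(genes_df) <- NULL
  m <- match(genes_df$event_id, events_df$event_id)
  genes_df$insertion_branch <- events_df$branch[m]
  genes_df$donor_genus <- events_df$donor_genus[m]
  genes_df$donor_order <- events_df$donor_order[m]
  genes_df$donor_phylum <- events_df$donor_phylum[m]

  list(genomes = genomes,
       truth = list(genes = genes_df, events = events_df,
                    inversions = if (length(inversions))
                      do.call(rbind, inversions) else
                        data.frame(genome_id = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE)),
       proteins = proteins,
       families = do.call(rbind, c(families, list(make.row.names = FALSE))),
       tree = config$tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup0 <- function(v, name) {
  if (!is.null(v) && !is.null(names(v)) && name %in% names(v)) v[[name]] else 0L
}

#' Simulate a ranked homology-hit table consistent with transfer truth
#'
#' For each protein-coding gene in the truth table, draws a ranked list of
#' protein homology hits whose taxonomy structure encodes the gene's status:
#' native genes have a same-genus best hit and a same-genus majority among the
#' top five; recently acquired genes have a donor-genus best hit and a
#' non-self majority; anciently acquired genes have a same-genus best hit
#' (sister strains carry the gene) but a non-self majority. Informative hits
#' are drawn strictly above the retention thresholds (coverage 0.90,
#' similarity 40); each gene also receives decoy hits strictly below them and
#' a self-genome hit, both of which the screen must discard.
#'
#' @param truth The `truth$genes` data.frame from [simulate_clade()] (or any
#'   data.frame with gene_id, genome_id, status, donor_* columns).
#' @param taxonomy data.frame(genome_id, genus, order, phylum); every genome
#'   in `truth` must appear.
#' @param self_genus Genus label shared by the clade.
#' @param seed Integer seed.
#' @return data.frame of hits with columns query_gene, query_genome,
#'   subject_id, subject_genome, subject_genus, subject_order, subject_phylum,
#'   metagenomic_flag, percent_similarity, percent_identity, hsp_query_cov,
#'   bitscore, rank.
#' @export
simulate_hit_table <- function(truth, taxonomy,
                               self_genus = "Thermosynechococcus", seed = 1L) {
  missing <- setdiff(unique(truth$genome_id), taxonomy$genome_id)
  if (length(missing))
    stop(sprintf("genome '%s' in truth has no taxonomy entry", missing[1]))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  if (nrow(truth) == 0L) return(empty_hit_table())
  other <- default_donor_pool()
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    gi <- truth[i, ]
    self_gen <- setdiff(taxonomy$genome_id, gi$genome_id)
    if (length(self_gen) == 0L) self_gen <- paste0(gi$genome_id, "_dup")
    self_hit <- function(rank) {
      src <- sample(self_gen, 1L)
      data.frame(subject_id = sprintf("%s|h%d", src, rank),
                 subject_genome = src, subject_genus = self_genus,
                 subject_order = taxonomy$order[1],
                 subject_phylum = taxonomy$phylum[1],
                 stringsAsFactors = FALSE)
    }
    foreign_hit <- function(rank, genus, ord, phy) {
      data.frame(subject_id = sprintf("nr|%s|%s|h%d", genus, gi$gene_id, rank),
                 subject_genome = NA_character_, subject_genus = genus,
                 subject_order = ord, subject_phylum = phy,
                 stringsAsFactors = FALSE)
    }
    rand_foreign <- function(rank) {
      j <- sample.int(nrow(other), 1L)
      foreign_hit(rank, other$genus[j], other$order[j], other$phylum[j])
    }
    top <- switch(gi$status,
      native = {
        n_f <- sample(0:2, 1L)  # never a non-self majority
        picks <- c(list(self_hit(1L)),
                   lapply(2:5, function(r)
                     if (r > 5L - n_f) rand_foreign(r) else self_hit(r)))
        do.call(rbind, picks)
      },
      hgt_recent = {
        n_f <- sample(3:5, 1L)
        picks <- lapply(1:5, function(r)
          if (r <= n_f) foreign_hit(r, gi$donor_genus, gi$donor_order,
                                    gi$donor_phylum) else self_hit(r))
        do.call(rbind, picks)
      },
      hgt_ancestral = {
        n_f <- sample(3:4, 1L)
        picks <- c(list(self_hit(1L)),
                   lapply(2:5, function(r)
                     if (r <= n_f + 1L)
                       foreign_hit(r, gi$donor_genus, gi$donor_order,
                                   gi$donor_phylum) else self_hit(r)))
        do.call(rbind, picks)
      },
      stop(sprintf("unknown status '%s' for gene '%s'", gi$status, gi$gene_id)))
    n_top <- nrow(top)
    top$hsp_query_cov <- runif(n_top, 0.92, 1.0)
    top$percent_similarity <- sort(runif(n_top, 45, 95), decreasing = TRUE)
    # decoys: good taxonomy but below one retention threshold each
    decoys <- rbind(rand_foreign(6L), rand_foreign(7L))
    decoys$hsp_query_cov <- c(runif(1, 0.3, 0.88), runif(1, 0.92, 1.0))
    decoys$percent_similarity <- c(runif(1, 45, 95), runif(1, 10, 38))
    # a self-genome hit (the gene itself) that must be excluded before ranking
    selfrow <- data.frame(subject_id = gi$gene_id, subject_genome = gi$genome_id,
                          subject_genus = self_genus,
                          subject_order = taxonomy$order[1],
                          subject_phylum = taxonomy$phylum[1],
                          hsp_query_cov = 1.0, percent_similarity = 100,
                          stringsAsFactors = FALSE)
    h <- rbind(selfrow, top, decoys)
    h$percent_identity <- pmax(5, h$percent_similarity - runif(nrow(h), 5, 15))
    h$bitscore <- round(seq(900, 200, length.out = nrow(h)) +
                          runif(nrow(h), 0, 10), 1)
    h$rank <- seq_len(nrow(h))
    h$metagenomic_flag <- FALSE
    h$query_gene <- gi$gene_id
    h$query_genome <- gi$genome_id
    rows[[i]] <- h
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("query_gene", "query_genome", "subject_id", "subject_genome",
          "subject_genus", "subject_order", "subject_phylum",
          "metagenomic_flag", "percent_similarity", "percent_identity",
          "hsp_query_cov", "bitscore", "rank")]
}

empty_hit_table <- function() {
  data.frame(query_gene = character(), query_genome = character(),
             subject_id = character(), subject_genome = character(),
             subject_genus = character(), subject_order = character(),
             subject_phylum = character(), metagenomic_flag = logical(),
             percent_similarity = numeric(), percent_identity = numeric(),
             hsp_query_cov = numeric(), bitscore = numeric(),
             rank = integer(), stringsAsFactors = FALSE)
}
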