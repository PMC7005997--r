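#' @importFrom data.table := .N .SD
NULL

utils::globalVariables(c("i.x", "i.y", "jac", "a", "b", "ga", "gb", "shared",
                         "kmer", "gene"))

protein_kmers <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Cluster proteins into ortholog groups across genomes
#'
#' Pairwise similarity is the Jaccard index of amino-acid k-mer sets. Edges
#' are drawn between reciprocal best hits of every genome pair and between
#' same-genome pairs scoring at least as high as both members' best
#' between-genome hit (recent paralogs); connected components of this graph
#' are the ortholog clusters. Deterministic: ties in best-hit selection are
#' broken by lexicographic gene id.
#'
#' @param proteins Named list (by genome_id) of named character vectors,
#'   locus_tag to amino-acid sequence.
#' @param k Amino-acid k-mer size for the similarity measure.
#' @param min_jaccard Similarity floor below which no edge is considered.
#' @return An `ortholog_clusters` list: `membership` (data.frame cluster,
#'   genome_id, gene_id), `phyletic_matrix` (cluster x genome copy numbers).
#' @export
cluster_orthologs <- function(proteins, k = 4L, min_jaccard = 0.05) {
  genome_ids <- names(proteins)
  stopifnot(!is.null(genome_ids), all(nzchar(genome_ids)))
  prot <- data.table::rbindlist(lapply(genome_ids, function(g)
    data.table::data.table(gene = names(proteins[[g]]), genome = g,
                           seq = unname(proteins[[g]]))))
  data.table::setorder(prot, gene)
  kms <- lapply(prot$seq, protein_kmers, k = k)
  sizes <- lengths(kms)
  idx <- data.table::data.table(
    kmer = unlist(kms), i = rep(seq_len(nrow(prot)), sizes))
  # shared k-mer counts for every protein pair with at least one common k-mer
  pairs <- merge(idx, idx, by = "kmer", allow.cartesian = TRUE)[i.x < i.y]
  pairs <- pairs[, .(shared = .N), by = .(i.x, i.y)]
  pairs[, jac := shared / (sizes[i.x] + sizes[i.y] - shared)]
  pairs <- pairs[jac >= min_jaccard]
  edges <- matrix(integer(0), ncol = 2)
  if (nrow(pairs)) {
    both <- data.table::rbindlist(list(
      pairs[, .(a = i.x, b = i.y, jac)], pairs[, .(a = i.y, b = i.x, jac)]))
    both[, ga := prot$genome[a]][, gb := prot$genome[b]]
    between <- both[ga != gb]
    # reciprocal best hits per genome pair (ties -> smallest gene id)
    data.table::setorder(between, a, gb, -jac, b)
    best <- between[, .SD[1L], by = .(a, gb)]
    bkey <- paste(best$a, best$b)
    rbh <- best[paste(best$b, best$a) %in% bkey & best$a < best$b]
    # within-genome edges at least as strong as both members' best between hit
    bb <- between[, .(top = max(jac)), by = a]
    topof <- setNames(bb$top, bb$a)
    within <- both[ga == gb & a < b]
    if (nrow(within)) {
      ta <- topof[as.character(within$a)]; tb <- topof[as.character(within$b)]
      ta[is.na(ta)] <- 0; tb[is.na(tb)] <- 0
      within <- within[jac >= pmax(ta, tb)]
    }
    edges <- rbind(as.matrix(rbh[, .(a, b)]),
                   as.matrix(within[, .(a, b)]))
  }
  verts <- data.frame(name = as.character(seq_len(nrow(prot))))
  ed <- data.frame(from = as.character(edges[, 1]),
                   to = as.character(edges[, 2]))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  comp <- igraph::components(g)
  member <- comp$membership[as.character(seq_len(nrow(prot)))]
  # stable cluster ids: order components by their smallest gene id
  first_gene <- tapply(prot$gene, member, min)
  remap <- setNames(rank(first_gene), names(first_gene))
  cl <- sprintf("OC%05d", remap[as.character(member)])
  membership <- data.frame(cluster = cl, genome_id = prot$genome,
                           gene_id = prot$gene, stringsAsFactors = FALSE)
  membership <- membership[order(membership$cluster, membership$genome_id,
                                 membership$gene_id), ]
  rownames(membership) <- NULL
  mat <- table(membership$cluster, membership$genome_id)
  pm <- matrix(as.integer(mat), nrow = nrow(mat),
               dimnames = list(rownames(mat), colnames(mat)))
  pm <- pm[, genome_ids, drop = FALSE]
  structure(list(membership = membership, phyletic_matrix = pm),
            class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat(sprintf("<ortholog_clusters> %d clusters over %d genomes (%d genes)\n",
              nrow(x$phyletic_matrix), ncol(x$phyletic_matrix),
              nrow(x$membership)))
  invisible(x)
}

#' Core and single-copy-core clusters
#'
#' @param clusters An `ortholog_clusters` object or a phyletic copy-number
#'   matrix (clusters x genomes).
#' @return List `core` (cluster ids present in every genome) and
#'   `single_copy_core` (exactly one copy in every genome; a subset of core).
#' @export
core_and_single_copy <- function(clusters) {
  pm <- phyletic_of(clusters)
  if (ncol(pm) == 0L) stop("empty genome list")
  core <- rownames(pm)[rowSums(pm > 0) == ncol(pm)]
  single <- rownames(pm)[rowSums(pm == 1) == ncol(pm)]
  list(core = core, single_copy_core = single)
}

phyletic_of <- function(x) {
  if (inherits(x, "ortholog_clusters")) x$phyletic_matrix else as.matrix(x)
}

#' Clusters found in exactly one genome
#'
#' @param clusters As in [core_and_single_copy()].
#' @return Named integer vector: per genome, the number of clusters whose
#'   members all lie in that genome.
#' @export
unique_per_genome <- function(clusters) {
  pm <- phyletic_of(clusters)
  present <- pm > 0
  uniq <- rowSums(present) == 1L
  counts <- colSums(present[uniq, , drop = FALSE])
  setNames(as.integer(counts), colnames(pm))
}

#' Branch-wise uniquely present / uniquely absent cluster counts
#'
#' For every branch of a rooted species tree, with daughter leaf set D:
#' uniquely present counts clusters present (>= 1 copy) in every genome of D
#' and absent from all other genomes; uniquely absent counts clusters absent
#' from every genome of D and present in all others. These are the "+" and
#' "-" numbers drawn on pangenome phylogenies.
#'
#' @param tree Rooted `phylo` (or Newick string) whose tips equal the matrix
#'   genomes exactly.
#' @param clusters As in [core_and_single_copy()].
#' @return data.frame: branch (sorted daughter leaf labels joined by "|"),
#'   n_leaves, n_uniquely_present, n_uniquely_absent.
#' @export
branch_unique_counts <- function(tree, clusters) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  pm <- phyletic_of(clusters)
  if (!setequal(tree$tip.label, colnames(pm))) {
    stop(sprintf("tree/matrix genome mismatch: only in tree [%s]; only in matrix [%s]",
                 paste(setdiff(tree$tip.label, colnames(pm)), collapse = ","),
                 paste(setdiff(colnames(pm), tree$tip.label), collapse = ",")))
  }
  present <- pm[, tree$tip.label, drop = FALSE] > 0
  ntip <- length(tree$tip.label)
  rows <- lapply(tree$edge[, 2L], function(child) {
    leaves <- if (child <= ntip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    din <- colnames(present) %in% leaves
    up <- sum(rowSums(present[, din, drop = FALSE]) == sum(din) &
                rowSums(present[, !din, drop = FALSE]) == 0L)
    ua <- sum(rowSums(present[, din, drop = FALSE]) == 0L &
                rowSums(present[, !din, drop = FALSE]) == sum(!din))
    data.frame(branch = paste(sort(leaves), collapse = "|"),
               n_leaves = sum(din), n_uniquely_present = up,
               n_uniquely_absent = ua, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concatenate single-copy-core protein families into a supermatrix
#'
#' @param clusters An `ortholog_clusters` object.
#' @param proteins As in [cluster_orthologs()]; family members must have equal
#'   length across genomes (pre-aligned or indel-free).
#' @param cluster_ids Clusters to concatenate (default: the single-copy core).
#' @return List `sequences` (named character vector, one per genome),
#'   `n_sites`, `cluster_ids` (in concatenation order).
#' @export
concatenate_core <- function(clusters, proteins, cluster_ids = NULL) {
  if (is.null(cluster_ids))
    cluster_ids <- core_and_single_copy(clusters)$single_copy_core
  if (length(cluster_ids) == 0L) stop("no families to concatenate")
  genome_ids <- colnames(clusters$phyletic_matrix)
  mem <- clusters$membership
  parts <- setNames(vector("list", length(genome_ids)), genome_ids)
  for (cid in sort(cluster_ids)) {
    rows <- mem[mem$cluster == cid, ]
    seqs <- setNames(
      mapply(function(g, gene) proteins[[g]][[gene]], rows$genome_id,
             rows$gene_id),
      rows$genome_id)
    if (length(unique(nchar(seqs))) != 1L)
      stop(sprintf("ragged family '%s': member lengths differ", cid))
    if (!setequal(names(seqs), genome_ids))
      stop(sprintf("family '%s' is not single-copy core", cid))
    for (g in genome_ids) parts[[g]] <- c(parts[[g]], seqs[[g]])
  }
  sequences <- vapply(parts, paste, "", collapse = "")
  list(sequences = sequences, n_sites = nchar(sequences[[1]]),
       cluster_ids = sort(cluster_ids))
}

poisson_distances <- function(mat, cols = NULL) {
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(mat[i, ] != mat[j, ])
    p <- min(p, 1 - 1e-9)   # ceiling for saturated pairs
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining core-genome tree with column bootstrap
#'
#' Distances are Poisson-corrected protein p-distances, d = -ln(1 - p), with p
#' capped just below 1 for saturated pairs. The tree is built by
#' neighbor-joining, rooted on the outgroup, and internal-branch support is
#' the percentage of column-resampled bootstrap replicates whose NJ tree
#' contains the same bipartition.
#'
#' @param supermatrix Output of [concatenate_core()] (or a named character
#'   vector of equal-length aligned sequences).
#' @param outgroup Taxon label used to root the tree.
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer seed for the column resampling.
#' @return List `tree` (rooted `phylo` with `node.label` percentages on
#'   internal nodes) and `support` (numeric vector of internal-node supports).
#' @export
distance_tree <- function(supermatrix, outgroup, n_bootstrap = 1000L,
                          seed = 1L) {
  seqs <- if (is.list(supermatrix)) supermatrix$sequences else supermatrix
  if (length(seqs) < 3L) stop("need at least 3 taxa")
  if (!outgroup %in% names(seqs)) stop(sprintf("outgroup '%s' not among taxa",
                                               outgroup))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  d <- poisson_distances(mat)
  if (all(d == 0)) warning("all sequences identical: star-like tree")
  main <- ape::nj(as.dist(d))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  boots <- vector("list", n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    boots[[b]] <- ape::nj(as.dist(poisson_distances(mat, cols)))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_bootstrap, 1)
  main$node.label <- as.character(support)
  rooted <- ape::root(main, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  list(tree = rooted, support = support)
}
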