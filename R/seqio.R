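#' @importFrom utils download.file head tail write.table read.table
#' @importFrom stats runif rbinom rpois rnorm setNames sd quantile median
NULL

GENE_FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "pseudogene", "mobile_element")

#' Construct a genome object
#'
#' A genome couples a DNA sequence with a circularity flag and a table of gene
#' annotations held in 0-based half-open coordinates. All on-disk formats keep
#' their native conventions (GFF3 and GenBank are 1-based inclusive); the
#' conversion happens exactly once, in the readers and writers.
#'
#' @param genome_id Character scalar identifier.
#' @param sequence DNA string over A, C, G, T, N. Lowercase input is folded to
#'   uppercase; any other character is rejected with its position.
#' @param circular Logical; whether the chromosome is circular.
#' @param annotations A data.frame as returned by [gene_table()]:
#'   columns `locus_tag`, `start`, `end` (0-based half-open), `strand`
#'   (`+`/`-`), `feature_kind`, `product`, `cog_category`.
#' @return An object of class `genome`.
#' @export
genome <- function(genome_id, sequence, circular = TRUE,
                   annotations = gene_table()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("genome '%s': disallowed character '%s' at position %d",
                 genome_id, substr(sequence, bad, bad), bad))
  }
  if (nchar(sequence) == 0L) stop(sprintf("genome '%s': empty sequence", genome_id))
  g <- structure(list(genome_id = genome_id, sequence = sequence,
                      circular = isTRUE(circular), annotations = annotations),
                 class = "genome")
  validate_genome(g)
  g
}

#' Build (or validate) a gene annotation table
#'
#' @param locus_tag,start,end,strand,feature_kind,product,cog_category Vectors
#'   of equal length; `start`/`end` are 0-based half-open.
#' @return A data.frame with one row per feature.
#' @export
gene_table <- function(locus_tag = character(), start = integer(),
                       end = integer(), strand = character(),
                       feature_kind = character(), product = character(),
                       cog_category = character()) {
  n <- length(locus_tag)
  if (length(product) == 0L && n > 0L) product <- rep("hypothetical protein", n)
  if (length(cog_category) == 0L && n > 0L) cog_category <- rep(NA_character_, n)
  data.frame(locus_tag = as.character(locus_tag),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             feature_kind = as.character(feature_kind),
             product = as.character(product),
             cog_category = as.character(cog_category),
             stringsAsFactors = FALSE)
}

validate_genome <- function(g) {
  a <- g$annotations
  len <- nchar(g$sequence)
  if (nrow(a)) {
    if (anyDuplicated(a$locus_tag))
      stop(sprintf("genome '%s': duplicated locus_tag '%s'", g$genome_id,
                   a$locus_tag[anyDuplicated(a$locus_tag)]))
    if (any(a$start >= a$end))
      stop(sprintf("genome '%s': feature '%s' has start >= end", g$genome_id,
                   a$locus_tag[which(a$start >= a$end)[1]]))
    if (any(a$start < 0L) || any(a$end > len))
      stop(sprintf("genome '%s': feature '%s' outside sequence bounds",
                   g$genome_id,
                   a$locus_tag[which(a$start < 0L | a$end > len)[1]]))
    if (!all(a$feature_kind %in% GENE_FEATURE_KINDS))
      stop(sprintf("genome '%s': unknown feature_kind '%s'", g$genome_id,
                   setdiff(a$feature_kind, GENE_FEATURE_KINDS)[1]))
    if (any(a$feature_kind == "CDS" & !a$strand %in% c("+", "-")))
      stop(sprintf("genome '%s': CDS without strand", g$genome_id))
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s, %d features\n", x$genome_id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$annotations)))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param s DNA string over ACGTN (either case).
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}

#' Read genome skeletons from FASTA
#'
#' @param path FASTA file with one record per replicon.
#' @param circular Logical recycled over records.
#' @return List of `genome` objects (no annotations).
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop(sprintf("duplicate FASTA ids in %s: %s", path,
                                       ids[anyDuplicated(ids)]))
  circular <- rep_len(circular, length(set))
  out <- lapply(seq_along(set), function(i)
    genome(ids[i], as.character(set[[i]]), circular = circular[i]))
  names(out) <- ids
  out
}

#' Write genomes to FASTA (70-column wrapped)
#'
#' @param genomes A `genome` or list of them.
#' @param path Output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "genome_id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read GFF3 annotations onto a genome
#'
#' On-disk coordinates are 1-based inclusive and converted to the internal
#' 0-based half-open convention. Features beyond the sequence end are rejected.
#'
#' @param path GFF3 file.
#' @param genome A `genome` skeleton whose id matches the seqid column.
#' @return The genome with its `annotations` table filled.
#' @export
read_gff3 <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) { genome$annotations <- gene_table(); return(genome) }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("malformed GFF3 line %d: %d columns (expected 9)",
                 which(nf != 9L)[1], nf[nf != 9L][1]))
  m <- do.call(rbind, fields)
  keep <- m[, 1] == genome$genome_id
  m <- m[keep, , drop = FALSE]
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (any(end1 < start1)) stop("GFF3 feature with end < start")
  attr_get <- function(attrs, key) {
    val <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", attrs)
    ifelse(grepl(sprintf("(^|;)%s=", key), attrs), val, NA_character_)
  }
  ann <- gene_table(
    locus_tag = attr_get(m[, 9], "locus_tag"),
    start = start1 - 1L, end = end1, strand = m[, 7],
    feature_kind = m[, 3],
    product = ifelse(is.na(attr_get(m[, 9], "product")), "hypothetical protein",
                     attr_get(m[, 9], "product")),
    cog_category = attr_get(m[, 9], "cog_category"))
  genome$annotations <- ann
  validate_genome(genome)
  genome
}

#' Write a genome's annotations as GFF3
#'
#' @param genome A `genome` with annotations.
#' @param path Output file.
#' @export
write_gff3 <- function(genome, path) {
  a <- genome$annotations
  attrs <- sprintf("ID=%s;locus_tag=%s;product=%s%s", a$locus_tag, a$locus_tag,
                   a$product,
                   ifelse(is.na(a$cog_category), "",
                          paste0(";cog_category=", a$cog_category)))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$genome_id,
                     nchar(genome$sequence)),
             if (nrow(a)) sprintf("%s\tcladescope\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                  genome$genome_id, a$feature_kind,
                                  a$start + 1L, a$end, a$strand, attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (minimal) GenBank flat file
#'
#' Parses LOCUS length/topology, CDS and gene-like features with simple or
#' `complement(a..b)` locations, `/locus_tag`, `/product`, and the ORIGIN
#' sequence block. Join locations and other feature keys are ignored.
#'
#' @param path GenBank flat file.
#' @return A `genome` object.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  gid <- toks[2]
  circular <- any(grepl("circular", locus, ignore.case = TRUE))
  ori <- grep("^ORIGIN", lines)[1]
  stopifnot(!is.na(ori))
  seq_lines <- lines[(ori + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  feat0 <- grep("^FEATURES", lines)[1]
  kinds <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
             mobile_element = "mobile_element")
  recs <- list()
  if (!is.na(feat0)) {
    body <- lines[(feat0 + 1L):(ori - 1L)]
    starts <- grep("^ {5}\\S", body)
    bounds <- c(starts, length(body) + 1L)
    for (i in seq_along(starts)) {
      block <- body[starts[i]:(bounds[i + 1L] - 1L)]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1])
      if (!key %in% names(kinds)) next
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L) next
      qual <- paste(block[-1], collapse = " ")
      get_q <- function(q) {
        m <- regmatches(qual, regexpr(sprintf('/%s="[^"]*"', q), qual))
        if (length(m)) sub(sprintf('/%s="([^"]*)"', q), "\\1", m) else NA_character_
      }
      recs[[length(recs) + 1L]] <- list(
        locus_tag = get_q("locus_tag"), start = as.integer(nums[1]) - 1L,
        end = as.integer(nums[length(nums)]), strand = strand,
        feature_kind = kinds[[key]],
        product = if (is.na(get_q("product"))) "hypothetical protein" else get_q("product"))
    }
  }
  ann <- if (length(recs)) {
    gene_table(locus_tag = vapply(recs, `[[`, "", "locus_tag"),
               start = vapply(recs, `[[`, 0L, "start"),
               end = vapply(recs, `[[`, 0L, "end"),
               strand = vapply(recs, `[[`, "", "strand"),
               feature_kind = vapply(recs, `[[`, "", "feature_kind"),
               product = vapply(recs, `[[`, "", "product"))
  } else gene_table()
  genome(gid, sequence, circular = circular, annotations = ann)
}

#' Write a genome as a minimal GenBank flat file
#'
#' Emits LOCUS, FEATURES (CDS and friends with locus_tag/product qualifiers)
#' and ORIGIN blocks sufficient for [read_genbank()] round trips.
#'
#' @param genome A `genome`.
#' @param path Output file.
#' @export
write_genbank <- function(genome, path) {
  a <- genome$annotations
  topo <- if (genome$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   BCT", genome$genome_id,
                   nchar(genome$sequence), topo),
           sprintf("DEFINITION  %s.", genome$genome_id),
           "FEATURES             Location/Qualifiers")
  if (nrow(a)) {
    loc <- ifelse(a$strand == "-",
                  sprintf("complement(%d..%d)", a$start + 1L, a$end),
                  sprintf("%d..%d", a$start + 1L, a$end))
    for (i in seq_len(nrow(a))) {
      out <- c(out,
               sprintf("     %-16s%s", a$feature_kind[i], loc[i]),
               sprintf('                     /locus_tag="%s"', a$locus_tag[i]),
               sprintf('                     /product="%s"', a$product[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- genome$sequence
  n <- nchar(s)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Fetch a nucleotide sequence from GenBank as FASTA
#'
#' Downloads `accession` via the NCBI efetch service. Requires network access;
#' errors otherwise.
#'
#' @param accession GenBank nucleotide accession, e.g. `"CP040671"`.
#' @param dest Destination FASTA path.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_fasta <- function(accession, dest) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  old <- options(timeout = 60); on.exit(options(old))
  status <- tryCatch(download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) 1L, warning = function(w) 1L)
  if (status != 0L || !file.exists(dest) || file.size(dest) < 100) {
    unlink(dest)
    stop(sprintf("could not fetch accession %s from GenBank", accession))
  }
  invisible(dest)
}
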