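# Protein clusters (PCs) from all-vs-all similarity, profile-merged protein
# families (iPFs), and family-level utilities. The built-in aligner is a
# BLOSUM62 Smith-Waterman with a Karlin-Altschul bit-score conversion so the
# graph can be built without an external search binary; tabular output from
# an external all-vs-all search is the production path. Profile-profile
# comparison itself is not reimplemented: only its tabular output is
# consumed, at the published merge thresholds.

# gapped BLOSUM62 Karlin-Altschul parameters
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.sw_bit_score <- function(raw) (.KA_LAMBDA * raw - log(.KA_K)) / log(2)

#' Build the protein similarity graph
#'
#' Edges are retained when the pair's best hit satisfies E <= 0.001 and bit
#' score >= 50, or bit score >= 30 when both proteins are <= 70 amino acids
#' (the short-protein rule). Self-hits are dropped and only the best hit per
#' unordered pair is kept.
#'
#' With `hits = NULL` the built-in aligner computes all-vs-all local
#' alignments (Smith-Waterman, BLOSUM62, gap open 11 / extend 1) and converts
#' raw scores to bits via the standard Karlin-Altschul parameters; E-values
#' use `query_length * db_size * 2^-bit`.
#'
#' @param proteins Named character vector (unique ids).
#' @param hits Optional external hit table with columns `query`, `subject`,
#'   `bit_score`, `e_value` (e.g. parsed 12-column tabular output via
#'   [parse_blast_tabular()]).
#' @param db_size Effective database size for the built-in E-value (default:
#'   total residue count).
#' @return `data.frame(protein_a, protein_b, bit_score, e_value, both_short)`.
#' @export
build_similarity_graph <- function(proteins, hits = NULL, db_size = NULL) {
  stopifnot(!is.null(names(proteins)), !anyDuplicated(names(proteins)))
  if (is.null(hits)) {
    ids <- names(proteins)
    if (is.null(db_size)) db_size <- sum(nchar(proteins))
    rows <- list()
    if (length(ids) >= 2L) for (i in 1:(length(ids) - 1L)) {
      alns <- Biostrings::pairwiseAlignment(
        pattern = unname(proteins[ids[(i + 1L):length(ids)]]),
        subject = unname(proteins[[ids[i]]]), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      bits <- .sw_bit_score(Biostrings::score(alns))
      rows[[i]] <- data.frame(
        query = ids[i], subject = ids[(i + 1L):length(ids)],
        bit_score = bits,
        e_value = nchar(proteins[[ids[i]]]) * db_size * 2^(-bits),
        stringsAsFactors = FALSE)
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query = character(), subject = character(),
                 bit_score = double(), e_value = double())
  }
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  if (nrow(hits)) {
    a <- pmin(hits$query, hits$subject)
    b <- pmax(hits$query, hits$subject)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -hits$bit_score)
    hits <- hits[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    a <- pmin(hits$query, hits$subject); b <- pmax(hits$query, hits$subject)
    len <- nchar(proteins)
    both_short <- len[a] <= 70L & len[b] <= 70L
    keep <- hits$e_value <= 0.001 &
      (hits$bit_score >= 50 | (both_short & hits$bit_score >= 30))
    out <- data.frame(protein_a = a, protein_b = b,
                      bit_score = hits$bit_score, e_value = hits$e_value,
                      both_short = unname(both_short),
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  data.frame(protein_a = character(), protein_b = character(),
             bit_score = double(), e_value = double(),
             both_short = logical(), stringsAsFactors = FALSE)
}

#' Parse 12-column tabular alignment output (outfmt-6 dialect)
#'
#' @param path Path to a tab-separated file with the standard 12 columns
#'   (query, subject, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore), no header.
#' @return `data.frame(query, subject, bit_score, e_value)`.
#' @export
parse_blast_tabular <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 12L)
  data.frame(query = as.character(tab[[1L]]), subject = as.character(tab[[2L]]),
             bit_score = as.numeric(tab[[12L]]), e_value = as.numeric(tab[[11L]]),
             stringsAsFactors = FALSE)
}

#' Cluster the similarity graph into protein clusters (PCs)
#'
#' Community detection (Infomap, the map-equation approach) on the similarity
#' graph; communities with at least 2 members become PCs, size-1 communities
#' and unconnected proteins are tracked as singletons. Deterministic given
#' `seed`.
#'
#' @param edges Edge table from [build_similarity_graph()].
#' @param proteins Named character vector (or bare ids) of all proteins,
#'   connected or not.
#' @param seed Random seed.
#' @return `list(pcs = named list pc_id -> member ids, singletons = ids,
#'   membership = named vector protein -> pc_id or NA)` of class
#'   `protein_clusters`.
#' @export
cluster_pcs <- function(edges, proteins, seed = 42L) {
  ids <- if (is.null(names(proteins))) as.character(proteins) else names(proteins)
  membership <- setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(edges) == 0L) {
    return(structure(list(pcs = list(), singletons = ids,
                          membership = membership),
                     class = "protein_clusters"))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE, vertices = ids)
  set.seed(seed)
  comm <- igraph::cluster_infomap(g)
  mem <- igraph::membership(comm)
  groups <- split(names(mem), as.integer(mem))
  sizes <- lengths(groups)
  multi <- groups[sizes >= 2L]
  # stable ids: by size descending, then smallest member id
  ord <- order(-lengths(multi),
               vapply(multi, function(x) min(x), character(1)))
  multi <- multi[ord]
  pcs <- setNames(lapply(multi, sort), sprintf("PC_%04d", seq_along(multi)))
  for (pid in names(pcs)) membership[pcs[[pid]]] <- pid
  structure(list(pcs = pcs, singletons = ids[is.na(membership)],
                 membership = membership),
            class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat("<protein_clusters> ", length(x$pcs), " PC(s), ",
      length(x$singletons), " singleton(s)\n", sep = "")
  invisible(x)
}

#' Merge PCs into iPFs via profile-profile hits
#'
#' A hit qualifies when probability >= 90% with coverage >= 50%, or
#' probability >= 99% with coverage >= 20% and hit length >= 100. iPFs are
#' the connected components of the qualifying-hit graph (single-link
#' transitive closure), so the result is invariant to hit ordering.
#'
#' @param pc_ids Character vector of all PC ids (e.g. `names(pcs$pcs)`).
#' @param profile_hits `data.frame(pc_a, pc_b, probability (percent),
#'   coverage (fraction), hit_length)`.
#' @return `data.frame(pc_id, ipf_id)`; every PC appears exactly once.
#' @export
merge_ipfs <- function(pc_ids, profile_hits = NULL) {
  stopifnot(!anyDuplicated(pc_ids))
  edges <- NULL
  if (!is.null(profile_hits) && nrow(profile_hits)) {
    stopifnot(all(c(profile_hits$pc_a, profile_hits$pc_b) %in% pc_ids))
    q <- (profile_hits$probability >= 90 & profile_hits$coverage >= 0.5) |
      (profile_hits$probability >= 99 & profile_hits$coverage >= 0.2 &
         profile_hits$hit_length >= 100)
    edges <- profile_hits[q, c("pc_a", "pc_b"), drop = FALSE]
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(pc_ids)
  if (!is.null(edges) && nrow(edges))
    g <- g + igraph::edges(as.vector(rbind(edges$pc_a, edges$pc_b)))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(x) min(x), character(1)))
  groups <- groups[ord]
  ipf <- setNames(rep(sprintf("iPF_%04d", seq_along(groups)), lengths(groups)),
                  unlist(groups, use.names = FALSE))
  data.frame(pc_id = pc_ids, ipf_id = unname(ipf[pc_ids]),
             stringsAsFactors = FALSE)
}

#' Filter partial-length sequences
#'
#' Computes the average length excluding the top and bottom 10% of the
#' length distribution (floor(0.1 n) values trimmed on each side) and drops
#' sequences shorter than half that trimmed mean. Idempotent.
#'
#' @param x Named character vector of sequences, or named numeric lengths.
#' @return The retained elements of `x` (same type).
#' @export
filter_partial_sequences <- function(x) {
  stopifnot(length(x) >= 1L)
  lens <- if (is.character(x)) nchar(x) else as.numeric(x)
  n <- length(lens)
  trim <- floor(0.1 * n)
  s <- sort(lens)
  core <- if (trim > 0L) s[(trim + 1L):(n - trim)] else s
  x[lens >= 0.5 * mean(core)]
}

#' Compile iPF annotation labels from member annotations
#'
#' Each iPF is labelled with the most frequent non-empty member label;
#' all-empty iPFs stay unlabelled (`NA`). Ties are resolved to the
#' lexicographically first label and flagged ambiguous.
#'
#' @param members Named list: ipf_id -> member protein ids.
#' @param labels Named character vector: protein id -> label (`""` = none).
#' @return `data.frame(ipf_id, label, ambiguous)`.
#' @export
annotate_ipfs <- function(members, labels) {
  out <- lapply(names(members), function(ipf) {
    lab <- labels[members[[ipf]]]
    lab <- lab[!is.na(lab) & nzchar(lab)]
    if (length(lab) == 0L)
      return(data.frame(ipf_id = ipf, label = NA_character_,
                        ambiguous = FALSE, stringsAsFactors = FALSE))
    tab <- table(lab)
    best <- tab[tab == max(tab)]
    data.frame(ipf_id = ipf, label = sort(names(best))[1L],
               ambiguous = length(best) > 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen for toxin-antitoxin gene pairs
#'
#' For each toxin-annotated gene, reports genes at most one intervening gene
#' away on the same contig. Unannotated iPFs observed next to the same toxin
#' iPF in at least `min_genomes` distinct genomes are called putative
#' antitoxins.
#'
#' @param gene_tables Named list (genome id -> `data.frame` with columns
#'   `gene_id`, `ipf_id`, `label`, optional `contig_id`), genes in genomic
#'   order.
#' @param max_intervening Maximum genes between toxin and partner (default 1).
#' @param min_genomes Distinct-genome support for a putative antitoxin call.
#' @return `list(pairs = data.frame(genome, toxin_gene, toxin_ipf,
#'   partner_gene, partner_ipf, partner_label, distance),
#'   putative_antitoxins = data.frame(ipf_id, toxin_ipf, n_genomes))`.
#' @export
find_ta_pairs <- function(gene_tables, max_intervening = 1L, min_genomes = 2L) {
  pair_rows <- list()
  for (gn in names(gene_tables)) {
    tab <- gene_tables[[gn]]
    if (is.null(tab$contig_id)) tab$contig_id <- "contig"
    lab <- tolower(ifelse(is.na(tab$label), "", tab$label))
    is_toxin <- grepl("toxin", lab, fixed = TRUE) &
      !grepl("antitoxin", lab, fixed = TRUE)
    for (t in which(is_toxin)) {
      near <- which(tab$contig_id == tab$contig_id[t] &
                      abs(seq_len(nrow(tab)) - t) >= 1L &
                      abs(seq_len(nrow(tab)) - t) <= max_intervening + 1L)
      for (p in near) {
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          genome = gn, toxin_gene = tab$gene_id[t],
          toxin_ipf = tab$ipf_id[t],
          partner_gene = tab$gene_id[p], partner_ipf = tab$ipf_id[p],
          partner_label = ifelse(nzchar(lab[p]), tab$label[p], ""),
          distance = abs(p - t) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(genome = character(), toxin_gene = character(),
               toxin_ipf = character(), partner_gene = character(),
               partner_ipf = character(), partner_label = character(),
               distance = integer(), stringsAsFactors = FALSE)
  un <- pairs[!nzchar(pairs$partner_label) & !is.na(pairs$partner_ipf), ,
              drop = FALSE]
  putative <- data.frame(ipf_id = character(), toxin_ipf = character(),
                         n_genomes = integer(), stringsAsFactors = FALSE)
  if (nrow(un)) {
    key <- paste(un$partner_ipf, un$toxin_ipf, sep = "\r")
    counts <- tapply(un$genome, key, function(g) length(unique(g)))
    keep <- counts >= min_genomes
    if (any(keep)) {
      parts <- strsplit(names(counts)[keep], "\r", fixed = TRUE)
      putative <- data.frame(
        ipf_id = vapply(parts, `[[`, character(1), 1L),
        toxin_ipf = vapply(parts, `[[`, character(1), 2L),
        n_genomes = as.integer(counts[keep]), stringsAsFactors = FALSE)
      rownames(putative) <- NULL
    }
  }
  list(pairs = pairs, putative_antitoxins = putative)
}
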