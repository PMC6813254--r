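# Host-interaction screens: CRISPR spacer-protospacer matching with
# cas-context filtering and self-targeting flags, Caudovirales co-infection
# via terminase markers, and prevalence/co-occurrence after host
# dereplication. Spacer matching is an exact <=1-mismatch Hamming scan: for
# short queries this is strictly more sensitive than the seeded heuristic it
# replaces and matches the published post-filter semantics (no indels).

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all placements of spacer on target with Hamming distance <= max_mm;
# returns data.frame(start (0-based), mismatches)
.hamming_scan <- function(spacer, target, max_mm = 1L) {
  m <- nchar(spacer); n <- nchar(target)
  if (n < m) return(data.frame(start = integer(), mismatches = integer()))
  sv <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  tv <- strsplit(target, "", fixed = TRUE)[[1L]]
  n_off <- n - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m))
    mm <- mm + (tv[j:(j + n_off - 1L)] != sv[j])
  keep <- which(mm <= max_mm)
  data.frame(start = keep - 1L, mismatches = mm[keep])
}

#' Match CRISPR spacers against prediction sequences
#'
#' Reports every full-length placement of each spacer, on either strand, with
#' at most one mismatch (Hamming distance; gaps are deliberately not
#' allowed). Coordinates are 0-based half-open on the forward strand of the
#' target. Per spacer, the best placement (fewest mismatches, then leftmost,
#' then target order) is flagged.
#'
#' @param spacers Named character vector of spacer sequences.
#' @param targets Named character vector of prediction sequences.
#' @param max_mm Maximum mismatches (default 1).
#' @return `data.frame(spacer_id, target_id, strand, start, end, mismatches,
#'   best)`.
#' @export
match_spacers <- function(spacers, targets, max_mm = 1L) {
  stopifnot(!is.null(names(spacers)), !is.null(names(targets)))
  rows <- list()
  for (sid in names(spacers)) {
    sp <- toupper(spacers[[sid]])
    rc <- .revcomp(sp)
    for (tid in names(targets)) {
      tg <- toupper(targets[[tid]])
      for (strand in c("+", "-")) {
        h <- .hamming_scan(if (strand == "+") sp else rc, tg, max_mm)
        if (nrow(h))
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = sid, target_id = tid, strand = strand,
            start = h$start, end = h$start + nchar(sp),
            mismatches = h$mismatches, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer_id = character(), target_id = character(),
               strand = character(), start = integer(), end = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  out$best <- logical(nrow(out))
  for (sid in unique(out$spacer_id)) {
    at <- which(out$spacer_id == sid)
    best <- at[order(out$mismatches[at], out$start[at])][1L]
    out$best[best] <- TRUE
  }
  rownames(out) <- NULL
  out
}

.default_cas_prefixes <- c("cas", "csn", "csy", "cmr", "cst")

#' Require a cas gene near the spacer locus
#'
#' Keeps matches whose spacer locus has at least one cas-labelled gene within
#' +-`window_bp` (default 10 kb) in the host annotation; such matches get
#' `cas_context = TRUE`. Spacers without genomic coordinates (metagenome-
#' derived) pass with `cas_context = FALSE`. Host-derived spacers whose
#' genome has no cas gene in range are removed.
#'
#' @param matches Output of [match_spacers()].
#' @param spacer_loci `data.frame(spacer_id, genome_id, start, end)`; `NA`
#'   coordinates mark metagenome-derived spacers.
#' @param genomes Named list of `annotated_genome` objects (host genomes).
#' @param window_bp Context window (default 10000).
#' @param cas_prefixes Case-insensitive label prefixes recognized as cas
#'   genes.
#' @return The retained matches with `cas_context` and `spacer_genome`
#'   columns.
#' @export
require_cas_context <- function(matches, spacer_loci, genomes,
                                window_bp = 10000L,
                                cas_prefixes = .default_cas_prefixes) {
  if (nrow(matches) == 0L) {
    matches$cas_context <- logical(0)
    matches$spacer_genome <- character(0)
    return(matches)
  }
  loci <- spacer_loci[match(matches$spacer_id, spacer_loci$spacer_id), ,
                      drop = FALSE]
  keep <- logical(nrow(matches))
  ctx <- logical(nrow(matches))
  for (r in seq_len(nrow(matches))) {
    if (is.na(loci$start[r]) || is.na(loci$genome_id[r])) {
      keep[r] <- TRUE; ctx[r] <- FALSE      # metagenome-derived: no locus
      next
    }
    gen <- genomes[[loci$genome_id[r]]]
    if (is.null(gen) || nrow(gen$genes) == 0L) next   # removed
    g <- gen$genes
    is_cas <- Reduce(`|`, lapply(cas_prefixes, function(p) {
      vapply(gene_labels(g$annotation), function(labs)
        any(startsWith(tolower(labs), p)), logical(1))
    }))
    lo <- loci$start[r] - window_bp; hi <- loci$end[r] + window_bp
    keep[r] <- ctx[r] <- any(is_cas & g$start < hi & g$end > lo)
  }
  out <- matches[keep, , drop = FALSE]
  out$cas_context <- ctx[keep]
  out$spacer_genome <- loci$genome_id[keep]
  rownames(out) <- NULL
  out
}

#' Flag self-targeting spacer matches
#'
#' A match is self-targeting when the spacer's host genome is the genome
#' carrying the matched provirus prediction. Matches whose prediction has no
#' host assignment (metagenome contigs) are flagged unresolved.
#'
#' @param matches Match table with a `spacer_genome` column (see
#'   [require_cas_context()]) or a `spacer_loci` argument.
#' @param prediction_hosts Named character vector: prediction/target id ->
#'   host genome id (`NA` = unknown).
#' @param spacer_loci Optional `data.frame(spacer_id, genome_id, ...)` used
#'   when `matches` lacks `spacer_genome`.
#' @return `matches` with `self_targeting` and `unresolved` columns.
#' @export
detect_self_targeting <- function(matches, prediction_hosts,
                                  spacer_loci = NULL) {
  if (is.null(matches$spacer_genome)) {
    stopifnot(!is.null(spacer_loci))
    matches$spacer_genome <-
      spacer_loci$genome_id[match(matches$spacer_id, spacer_loci$spacer_id)]
  }
  ph <- unname(prediction_hosts[matches$target_id])
  matches$unresolved <- is.na(ph) | is.na(matches$spacer_genome)
  matches$self_targeting <- !matches$unresolved & ph == matches$spacer_genome
  matches
}

#' Detect Caudovirales co-infection via terminase markers
#'
#' Scans the genome's translated genes against terminase marker models and
#' flags the genome when any protein scores at least `score_min` (bit score)
#' against any model. The number of distinct co-infecting prophages is
#' estimated as the number of terminase hits at least `merge_bp` apart
#' (closer hits on a contig are counted once).
#'
#' @param genome An `annotated_genome`.
#' @param terminase_models List of `marker_model`s.
#' @param score_min Bit-score threshold (default 30).
#' @param merge_bp Distance below which hits collapse (default 5000).
#' @return `list(flagged, n_prophages, hits)`.
#' @export
detect_caudovirales_coinfection <- function(genome, terminase_models,
                                            score_min = 30, merge_bp = 5000L) {
  hits <- scan_markers(genome, terminase_models)
  hits <- hits[hits$bit_score >= score_min, , drop = FALSE]
  n <- 0L
  if (nrow(hits)) {
    g <- genome$genes
    at <- match(hits$gene_id, g$gene_id)
    mids <- (g$start[at] + g$end[at]) / 2
    for (contig in unique(g$contig_id[at])) {
      m <- sort(mids[g$contig_id[at] == contig])
      n <- n + 1L + sum(diff(m) >= merge_bp)
    }
  }
  list(flagged = nrow(hits) > 0L, n_prophages = n, hits = hits)
}

#' Per-genus inovirus prevalence and co-occurrence
#'
#' Host genomes are dereplicated at 95% identity / 95% alignment fraction
#' ([dereplicate_hosts()]); a dereplicated cluster counts as inovirus-positive
#' when any member genome carries a detection. Prevalence per genus is the
#' fraction of positive clusters. The co-occurrence table gives, per positive
#' cluster, the number of distinct inovirus species detected.
#'
#' @param host_seqs Named character vector of host genome sequences.
#' @param genus Named character vector: genome id -> genus.
#' @param detections `data.frame(genome_id, species_id)`: one row per
#'   detection.
#' @return `list(prevalence = data.frame(genus, n_genomes, n_with_inovirus,
#'   prevalence), cooccurrence = data.frame(cluster_id, n_species),
#'   clusters)`.
#' @export
compute_prevalence <- function(host_seqs, genus, detections) {
  cl <- dereplicate_hosts(host_seqs)
  rep_of <- setNames(cl$cluster_id, cl$member)
  reps <- unique(cl[, c("cluster_id", "representative")])
  reps$genus <- unname(genus[reps$representative])
  det_cluster <- unname(rep_of[detections$genome_id])
  pos <- unique(det_cluster)
  prev <- do.call(rbind, lapply(split(reps, reps$genus), function(x) {
    data.frame(genus = x$genus[1L], n_genomes = nrow(x),
               n_with_inovirus = sum(x$cluster_id %in% pos),
               stringsAsFactors = FALSE)
  }))
  prev$prevalence <- prev$n_with_inovirus / prev$n_genomes
  rownames(prev) <- NULL
  cooc <- data.frame(cluster_id = character(), n_species = integer(),
                     stringsAsFactors = FALSE)
  if (nrow(detections)) {
    n_sp <- tapply(detections$species_id, det_cluster,
                   function(s) length(unique(s)))
    cooc <- data.frame(cluster_id = names(n_sp),
                       n_species = as.integer(n_sp), stringsAsFactors = FALSE)
    rownames(cooc) <- NULL
  }
  list(prevalence = prev, cooccurrence = cooc, clusters = cl)
}
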