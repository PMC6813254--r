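# pI-like morphogenesis-ATPase marker search. The default engine is an
# ungapped position-specific scoring matrix (PSSM) scan with a simple
# score -> E-value calibration; parsed hmmsearch --tblout output is the
# production path and goes through the same hit filter.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a marker model from a score matrix
#'
#' @param scores Numeric matrix, 20 rows (amino acids `A..Y` in the order of
#'   `Biostrings::AA_STANDARD`-compatible alphabet) by model length columns;
#'   all entries finite.
#' @param model_id Identifier.
#' @param origin `"seed"` or `"refined-round-<k>"`.
#' @return An object of class `marker_model`.
#' @export
marker_model <- function(scores, model_id, origin = "seed") {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == 20L, all(is.finite(scores)))
  rownames(scores) <- .AA20
  structure(list(scores = scores, model_id = model_id,
                 length = ncol(scores), origin = origin),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat("<marker_model> ", x$model_id, " (", x$length, " columns, ",
      x$origin, ")\n", sep = "")
  invisible(x)
}

#' Build a log-odds PSSM from one or more protein sequences
#'
#' With a single sequence the model is that sequence's log-odds profile. With
#' several, sequences are star-aligned onto the longest one (pairwise global
#' alignments, BLOSUM62), residue counts are accumulated per column of the
#' centre sequence, and log2 odds against a uniform background with a
#' pseudocount are taken. Model length equals the centre (ungapped consensus)
#' length. Deterministic.
#'
#' @param proteins Character vector of amino-acid sequences.
#' @param model_id Identifier for the resulting model.
#' @param origin Origin tag (see [marker_model()]).
#' @param pseudocount Added (background-weighted) count per cell.
#' @return A `marker_model`.
#' @export
build_pssm <- function(proteins, model_id, origin = "seed", pseudocount = 1) {
  proteins <- toupper(proteins)
  stopifnot(length(proteins) >= 1L, all(nzchar(proteins)))
  centre <- proteins[[which.max(nchar(proteins))]]
  L <- nchar(centre)
  counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  .add_seq <- function(aligned_to_centre) {
    # aligned_to_centre: character vector of length L (residue or NA)
    ok <- !is.na(aligned_to_centre) & aligned_to_centre %in% .AA20
    idx <- cbind(match(aligned_to_centre[ok], .AA20), which(ok))
    counts[idx] <<- counts[idx] + 1
  }
  for (p in proteins) {
    if (identical(p, centre)) {
      .add_seq(strsplit(centre, "", fixed = TRUE)[[1L]])
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = p, subject = centre, type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    keep <- sub != "-"
    col_res <- pat[keep]            # one entry per centre column
    col_res[col_res == "-"] <- NA_character_
    .add_seq(col_res)
  }
  n_col <- colSums(counts)
  bg <- 1 / 20
  scores <- log2(sweep(counts + pseudocount * bg, 2L,
                       (n_col + pseudocount) * bg, "/"))
  marker_model(scores, model_id = model_id, origin = origin)
}

#' Score a protein against a marker model (ungapped PSSM scan)
#'
#' The bit score is the maximum over all ungapped placements of the model on
#' the protein of the summed per-column log-odds. The E-value is calibrated
#' as `n_targets * 2^(-bit_score)` (overridable by supplying a different
#' `n_targets`). Unknown residues contribute 0 with a warning. Proteins
#' shorter than the model admit no placement and yield `NULL`.
#'
#' @param model A `marker_model`.
#' @param protein Amino-acid string (non-empty).
#' @param n_targets Effective search-space size for the E-value calibration.
#' @param gene_id Optional identifier carried into the hit.
#' @return One-row `data.frame` (`gene_id`, `model_id`, `bit_score`,
#'   `e_value`, `model_start`, `model_end`, `target_start`, `target_end`;
#'   1-based residue coordinates) or `NULL` if the protein is shorter than
#'   the model.
#' @export
score_profile <- function(model, protein, n_targets = 1, gene_id = NA_character_) {
  stopifnot(inherits(model, "marker_model"), nzchar(protein))
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  n <- length(res); L <- model$length
  if (n < L) return(NULL)
  idx <- match(res, .AA20)
  if (anyNA(idx))
    warning("unknown residue(s) in ", if (is.na(gene_id)) "protein" else gene_id,
            "; scored as 0")
  n_off <- n - L + 1L
  acc <- numeric(n_off)
  M <- model$scores
  for (j in seq_len(L)) {
    colscores <- M[, j][idx[j:(j + n_off - 1L)]]
    colscores[is.na(colscores)] <- 0
    acc <- acc + colscores
  }
  best <- which.max(acc)
  bit <- acc[[best]]
  data.frame(gene_id = gene_id, model_id = model$model_id,
             bit_score = bit, e_value = n_targets * 2^(-bit),
             model_start = 1L, model_end = L,
             target_start = best, target_end = best + L - 1L,
             stringsAsFactors = FALSE)
}

#' Scan all translated genes of a genome against marker models
#'
#' For each translated gene the best-scoring model placement per model is
#' recorded. `n_targets` defaults to the number of translated genes, the
#' search-space size the E-value calibration expects.
#'
#' @param genome An `annotated_genome`.
#' @param models A `marker_model` or list of them.
#' @param n_targets Optional E-value calibration size.
#' @return A hit `data.frame` (possibly zero rows).
#' @export
scan_markers <- function(genome, models, n_targets = NULL) {
  if (inherits(models, "marker_model")) models <- list(models)
  g <- genome$genes
  translated <- which(!is.na(g$translation) & nzchar(g$translation))
  if (is.null(n_targets)) n_targets <- max(1L, length(translated))
  hits <- list()
  for (i in translated) {
    for (m in models) {
      h <- score_profile(m, g$translation[i], n_targets = n_targets,
                         gene_id = g$gene_id[i])
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(), model_id = character(),
                      bit_score = double(), e_value = double(),
                      model_start = integer(), model_end = integer(),
                      target_start = integer(), target_end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Filter marker hits at the published thresholds
#'
#' Profile mode keeps hits with bit score >= 30 and E-value <= 0.001 (the
#' hmmsearch thresholds); singleton mode keeps bit score >= 50 (the blastp
#' threshold used for the one marker without a profile). Order-preserving and
#' idempotent.
#'
#' @param hits Hit `data.frame` with `bit_score` and `e_value` columns.
#' @param mode `"profile"` or `"singleton"`.
#' @return The retained rows, original order.
#' @export
filter_marker_hits <- function(hits, mode = c("profile", "singleton")) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) return(hits)
  keep <- if (mode == "profile") {
    hits$bit_score >= 30 & hits$e_value <= 0.001
  } else {
    hits$bit_score >= 50
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse hmmsearch --tblout output into the hit table dialect
#'
#' Consumes the whitespace-delimited per-target table written by hmmer's
#' `hmmsearch --tblout` (full-sequence E-value and score columns).
#'
#' @param path Path to a `--tblout` file.
#' @return Hit `data.frame` with `gene_id`, `model_id`, `bit_score`, `e_value`.
#' @export
parse_hmmsearch_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(), model_id = character(),
                      bit_score = double(), e_value = double(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(
    gene_id = vapply(fields, `[[`, character(1), 1L),
    model_id = vapply(fields, `[[`, character(1), 3L),
    bit_score = as.numeric(vapply(fields, `[[`, character(1), 6L)),
    e_value = as.numeric(vapply(fields, `[[`, character(1), 5L)),
    stringsAsFactors = FALSE)
}

#' Global percent identity over the shorter sequence
#'
#' Needleman-Wunsch alignment (BLOSUM62), identity = matches / length of the
#' shorter sequence — the cd-hit-style identity used for marker refinement.
#'
#' @param a,b Amino-acid strings.
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# greedy longest-first identity clustering (ties broken by name)
.greedy_identity_cluster <- function(proteins, threshold = 0.9) {
  stopifnot(!is.null(names(proteins)))
  ord <- order(-nchar(proteins), names(proteins))
  centroids <- character(0)
  assignment <- setNames(character(length(proteins)), names(proteins))
  for (i in ord) {
    id <- names(proteins)[i]
    placed <- FALSE
    for (cid in centroids) {
      if (seq_identity(proteins[[i]], proteins[[cid]]) >= threshold) {
        assignment[[id]] <- cid; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      assignment[[id]] <- id
    }
  }
  list(assignment = assignment, centroids = centroids)
}

#' Refine a marker model from validated pI proteins
#'
#' Mirrors the iterative profile-refinement protocol: cluster the validated
#' proteins at 90% amino-acid identity (greedy, longest-first centroids), keep
#' one representative per cluster, and rebuild the profile from the
#' representatives ([build_pssm()] star alignment). Requires at least two
#' sequences.
#'
#' @param proteins Named character vector of validated marker proteins.
#' @param round_id Refinement round number (tags the model origin).
#' @param identity Clustering identity threshold (default 0.9).
#' @param model_id Identifier for the refined model.
#' @return A `marker_model` with origin `"refined-round-<round_id>"`.
#' @export
refine_marker_models <- function(proteins, round_id, identity = 0.9,
                                 model_id = paste0("pI_refined_r", round_id)) {
  if (length(proteins) < 2L)
    stop("marker refinement needs at least 2 sequences")
  if (is.null(names(proteins)))
    names(proteins) <- paste0("p", seq_along(proteins))
  cl <- .greedy_identity_cluster(proteins, threshold = identity)
  reps <- unname(proteins[cl$centroids])
  model <- build_pssm(reps, model_id = model_id,
                      origin = paste0("refined-round-", round_id))
  attr(model, "n_clusters") <- length(cl$centroids)
  attr(model, "assignment") <- cl$assignment
  model
}

#' Classify pI TMD topology
#'
#' Canonical pI proteins anchor in the membrane through a C-terminal TMD; an
#' atypical class carries the TMD at the N terminus instead. A TMD whose
#' midpoint falls in the C-terminal third of the protein gives
#' `"canonical_C_terminal"` (checked first), one in the N-terminal third gives
#' `"atypical_N_terminal"`; no terminal TMD gives `"none"`.
#'
#' @param protein Amino-acid string.
#' @param tmds TMD span table from [predict_tmds()] (computed if missing).
#' @return One of `"canonical_C_terminal"`, `"atypical_N_terminal"`, `"none"`.
#' @export
classify_pi_topology <- function(protein, tmds = predict_tmds(protein)) {
  n <- nchar(protein)
  if (nrow(tmds) == 0L) return("none")
  mid <- (tmds$start + tmds$end) / 2
  if (any(mid > 2 * n / 3)) return("canonical_C_terminal")
  if (any(mid < n / 3)) return("atypical_N_terminal")
  "none"
}

.replication_keywords <- c("replication initiation", "rolling circle", "rcr")

#' Validate a candidate pI protein cluster
#'
#' A protein cluster is accepted as a genuine inovirus pI cluster when (a) a
#' majority of its members carry 1-2 TMDs (N- or C-terminal) and (b) at least
#' half of the members co-occur with another inovirus-expected gene class —
#' a replication-initiation annotation or a structural candidate — in their
#' genome neighbourhood. The reasons vector lists the failed criteria.
#'
#' @param proteins Named character vector of member protein sequences.
#' @param contexts List (one element per member, same order) of
#'   `list(labels = <character>, n_structural = <integer>)` describing the
#'   member's neighbouring genes.
#' @return `list(valid = <logical>, reasons = <character>)`.
#' @export
validate_pi_cluster <- function(proteins, contexts) {
  stopifnot(length(proteins) >= 1L, length(contexts) == length(proteins))
  n <- length(proteins)
  tmd_ok <- vapply(proteins, function(p) {
    k <- nrow(predict_tmds(p)); k >= 1L && k <= 2L
  }, logical(1))
  ctx_ok <- vapply(contexts, function(ctx) {
    labels <- ctx$labels %||% character(0)
    nst <- ctx$n_structural %||% 0L
    any(.labels_match(labels, .replication_keywords)) || nst >= 1L
  }, logical(1))
  reasons <- character(0)
  if (mean(tmd_ok) <= 0.5) reasons <- c(reasons, "no TMD majority")
  if (mean(ctx_ok) < 0.5) reasons <- c(reasons, "context")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
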