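# The core detection method: genome-context features around each pI-like
# marker hit, a random-forest window classifier, boundary delineation via
# direct-repeat att sites, and typed predictions.

.feature_names <- c("gene_density", "median_gene_len", "frac_short_genes",
                    "frac_unannotated", "n_structural", "frac_known_pc",
                    "mean_intergenic_gap", "strand_coherence",
                    "has_replication", "window_frac")

# Per-gene quantities for one contig, computed once and aggregated per window.
.gene_feature_table <- function(genome, contig_id, known_pc_hits = NULL) {
  g <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  n <- nrow(g)
  pc <- rep(FALSE, n)
  if (!is.null(known_pc_hits) && n > 0L) {
    if (!is.null(names(known_pc_hits))) {
      pc <- unname(known_pc_hits[g$gene_id])
      pc[is.na(pc)] <- FALSE
    } else {
      stopifnot(length(known_pc_hits) == n)
      pc <- as.logical(known_pc_hits)
    }
  }
  list(
    gene_id = g$gene_id,
    start = g$start, end = g$end,
    len = g$end - g$start,
    unannotated = !nzchar(g$annotation),
    structural = vapply(g$translation, is_candidate_structural, logical(1),
                        USE.NAMES = FALSE),
    pc_hit = pc,
    replication = .labels_match(g$annotation, .replication_keywords),
    plus_strand = g$strand == "+")
}

.window_feature_vector <- function(tbl, i, j) {
  idx <- i:j
  n <- length(idx)
  span_nt <- tbl$end[j] - tbl$start[i]
  gaps <- if (n > 1L) pmax(0L, tbl$start[idx[-1L]] - tbl$end[idx[-n]]) else 0L
  c(gene_density = n / (span_nt / 1000),
    median_gene_len = median(tbl$len[idx]),
    frac_short_genes = mean(tbl$len[idx] < 300L),
    frac_unannotated = mean(tbl$unannotated[idx]),
    n_structural = sum(tbl$structural[idx]),
    frac_known_pc = mean(tbl$pc_hit[idx]),
    mean_intergenic_gap = mean(gaps),
    strand_coherence = max(mean(tbl$plus_strand[idx]),
                           mean(!tbl$plus_strand[idx])),
    has_replication = as.numeric(any(tbl$replication[idx])),
    window_frac = n / 30)
}

#' Extract the 10 genome-context features for a gene window
#'
#' The feature set summarizes what distinguishes an inovirus genome from its
#' host background: gene density (genes/kb over the window span), median gene
#' length (nt), fraction of genes < 300 nt, fraction of unannotated
#' (hypothetical) genes, count of candidate structural proteins
#' ([is_candidate_structural()]), fraction of genes hitting known inovirus
#' protein clusters (caller-supplied flags), mean intergenic gap (bp, floored
#' at 0), strand coherence (modal-strand fraction), presence of a
#' replication-initiation annotation (0/1), and window size in genes / 30.
#'
#' @param genome An `annotated_genome`.
#' @param contig_id Contig to read the window from.
#' @param window Integer pair `c(i, j)`: first and last gene index (1-based,
#'   within the contig's gene list) of the window.
#' @param known_pc_hits Optional logical vector flagging genes similar to
#'   known inovirus protein clusters, either named by `gene_id` or positional
#'   per contig gene. `NULL` = all `FALSE`.
#' @return Named numeric vector of the 10 features.
#' @export
extract_features <- function(genome, contig_id, window, known_pc_hits = NULL) {
  tbl <- .gene_feature_table(genome, contig_id, known_pc_hits)
  stopifnot(length(window) == 2L, window[1L] >= 1L,
            window[2L] <= length(tbl$gene_id), window[1L] <= window[2L])
  .window_feature_vector(tbl, window[1L], window[2L])
}

#' Train the inovirus window classifier
#'
#' A random forest (default, 2000 trees, other parameters left at their
#' defaults) whose score for a window is the fraction of trees voting
#' "inovirus"; a logistic-regression baseline is available behind the same
#' interface. Reproducible given `seed`; errors if only one class is present.
#'
#' @param features Numeric matrix or data frame of feature vectors (rows =
#'   windows, columns as in [extract_features()]).
#' @param labels Factor or character with levels `"background"`/`"inovirus"`.
#' @param seed Random seed.
#' @param ntree Number of trees for the random-forest engine.
#' @param engine `"rf"` or `"logistic"`.
#' @return An object of class `inovirus_classifier` with a [predict][
#'   predict.inovirus_classifier()] method returning scores in `[0, 1]`.
#' @export
train_classifier <- function(features, labels, seed = 42L, ntree = 2000L,
                             engine = c("rf", "logistic")) {
  engine <- match.arg(engine)
  x <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("background", "inovirus"))
  if (anyNA(y)) stop("labels must be 'background' or 'inovirus'")
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  set.seed(seed)
  fit <- if (engine == "rf") {
    randomForest::randomForest(x, y, ntree = ntree)
  } else {
    df <- data.frame(x, .y = as.integer(y == "inovirus"))
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  }
  structure(list(fit = fit, engine = engine, features = colnames(x),
                 seed = seed, ntree = ntree),
            class = "inovirus_classifier")
}

#' Predict inovirus window scores
#'
#' @param object An `inovirus_classifier`.
#' @param newdata Feature matrix/data frame (columns as at training).
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]` (fraction of trees voting inovirus for
#'   the random-forest engine; fitted probability for the logistic baseline).
#' @export
predict.inovirus_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) x <- x[, object$features, drop = FALSE]
  if (object$engine == "rf") {
    unname(predict(object$fit, x, type = "prob")[, "inovirus"])
  } else {
    unname(predict(object$fit, newdata = as.data.frame(x), type = "response"))
  }
}

#' @export
print.inovirus_classifier <- function(x, ...) {
  cat("<inovirus_classifier> engine:", x$engine,
      if (x$engine == "rf") paste0("(", x$ntree, " trees)"), "\n")
  invisible(x)
}

# ROC from scores: thresholds descending; one point per distinct score.
.roc_points <- function(scores, labels) {
  pos <- labels == "inovirus"
  ord <- order(-scores)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # keep last index of each distinct score
  keep <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(threshold = c(Inf, scores[ord][keep]),
             fpr = c(0, fp[keep] / max(1L, sum(!pos))),
             tpr = c(0, tp[keep] / max(1L, sum(pos))))
}

.auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' k-fold cross-validation of the window classifier
#'
#' Partitions the samples into `k` folds whose sizes differ by at most one,
#' uses each fold exactly once for validation, pools the out-of-fold scores
#' into a single ROC curve, and reports the operating point used for model
#' selection: the best true-positive rate attainable at a false-positive rate
#' below 1%.
#'
#' @inheritParams train_classifier
#' @param k Number of folds (default 10); each class must have >= k samples.
#' @return `list(roc, auc, tpr_at_fpr1, scores, folds)` of class
#'   `inovirus_cv`.
#' @export
cross_validate <- function(features, labels, k = 10L, seed = 42L,
                           ntree = 2000L, engine = c("rf", "logistic")) {
  engine <- match.arg(engine)
  x <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("background", "inovirus"))
  n <- nrow(x)
  if (any(table(y) < k))
    stop("each class needs at least k samples for k-fold cross-validation")
  set.seed(seed)
  folds <- NULL
  for (try in 1:100) {
    cand <- sample(rep_len(seq_len(k), n))
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[cand != f])) == 2L, logical(1)))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds)) stop("could not build folds with both classes in training")
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- train_classifier(x[!test, , drop = FALSE], y[!test],
                            seed = seed + f, ntree = ntree, engine = engine)
    scores[test] <- predict(fit, x[test, , drop = FALSE])
  }
  roc <- .roc_points(scores, y)
  ok <- roc$fpr < 0.01
  structure(list(roc = roc, auc = .auc_trapezoid(roc),
                 tpr_at_fpr1 = if (any(ok)) max(roc$tpr[ok]) else 0,
                 scores = scores, folds = folds),
            class = "inovirus_cv")
}

#' @export
print.inovirus_cv <- function(x, ...) {
  cat("<inovirus_cv> AUC:", round(x$auc, 4),
      " TPR at FPR<1%:", round(x$tpr_at_fpr1, 4), "\n")
  invisible(x)
}

#' Sliding-window maximization around a pI gene
#'
#' Enumerates every gene interval that contains the pI gene and spans at most
#' `max_window` genes in total (truncated at contig ends; the per-side
#' interpretation is available via `mode = "per_side"`), scores each with the
#' classifier, and returns the maximum-scoring interval if its score exceeds
#' `min_score`, else `NULL`. Ties are broken towards the smallest interval,
#' then the leftmost.
#'
#' @param genome An `annotated_genome`.
#' @param contig_id Contig holding the pI gene.
#' @param pi_gene_index 1-based index of the pI gene within the contig's genes.
#' @param classifier An `inovirus_classifier`, or a function mapping a feature
#'   matrix to a score vector (useful for mock scorers).
#' @param known_pc_hits See [extract_features()].
#' @param max_window Maximum total window size in genes (default 30).
#' @param min_score Score that must be exceeded (default 0.9).
#' @param mode `"total"` (default: interval size <= max_window) or
#'   `"per_side"` (up to max_window genes on each side of pI).
#' @return `list(window = c(i, j), score = <numeric>)` or `NULL`.
#' @export
scan_windows <- function(genome, contig_id, pi_gene_index, classifier,
                         known_pc_hits = NULL, max_window = 30L,
                         min_score = 0.9, mode = c("total", "per_side")) {
  mode <- match.arg(mode)
  tbl <- .gene_feature_table(genome, contig_id, known_pc_hits)
  n <- length(tbl$gene_id)
  stopifnot(pi_gene_index >= 1L, pi_gene_index <= n)
  p <- pi_gene_index
  if (mode == "total") {
    lo <- max(1L, p - max_window + 1L); hi <- min(n, p + max_window - 1L)
    cand <- expand.grid(i = lo:p, j = p:hi)
    cand <- cand[cand$j - cand$i + 1L <= max_window, , drop = FALSE]
  } else {
    cand <- expand.grid(i = max(1L, p - max_window):p,
                        j = p:min(n, p + max_window))
  }
  feats <- t(vapply(seq_len(nrow(cand)), function(r)
    .window_feature_vector(tbl, cand$i[r], cand$j[r]),
    numeric(length(.feature_names))))
  scores <- if (is.function(classifier)) classifier(feats)
            else predict(classifier, feats)
  best <- max(scores)
  if (best <= min_score) return(NULL)
  at <- which(scores == best)
  size <- cand$j[at] - cand$i[at]
  at <- at[order(size, cand$i[at])][1L]
  list(window = c(cand$i[at], cand$j[at]), score = best)
}

#' Find candidate att sites as flanking direct repeats
#'
#' Reports all maximal exact direct repeats of length >= `min_repeat` with one
#' copy entirely in the left flank (up to `flank_bp` upstream of the span) and
#' one entirely in the right flank. Each repeat is annotated with its context:
#' `"tRNA"` if either copy overlaps a tRNA gene (the canonical integration
#' signature), `"non_integrase"` if the enclosed region contains an integrase
#' gene and neither copy lies inside it, else `"plain"`. Results are sorted by
#' repeat length (descending) then distance to the span (ascending).
#'
#' @param genome An `annotated_genome`.
#' @param contig_id Contig of the candidate region.
#' @param span Integer pair, 0-based half-open genomic span of the candidate.
#' @param flank_bp Flank search distance (default 20 kb, truncated at contig
#'   ends).
#' @param min_repeat Minimum repeat length (default 10 bp).
#' @return `data.frame` with `repeat_seq`, `length`, `left_start`, `left_end`,
#'   `right_start`, `right_end` (0-based half-open genomic), `context`,
#'   `distance`; zero rows if none.
#' @export
find_att_sites <- function(genome, contig_id, span, flank_bp = 20000L,
                           min_repeat = 10L) {
  seq <- genome$contigs[[contig_id]]
  n <- nchar(seq)
  stopifnot(span[1L] >= 0L, span[2L] <= n, span[1L] < span[2L])
  l0 <- max(0L, span[1L] - flank_bp)          # left flank [l0, span[1])
  r1 <- min(n, span[2L] + flank_bp)           # right flank [span[2], r1)
  empty <- data.frame(repeat_seq = character(), length = integer(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      context = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  nl <- span[1L] - l0; nr <- r1 - span[2L]
  if (nl < min_repeat || nr < min_repeat) return(empty)
  left <- substr(seq, l0 + 1L, span[1L])
  right <- substr(seq, span[2L] + 1L, r1)
  lv <- strsplit(left, "", fixed = TRUE)[[1L]]
  rv <- strsplit(right, "", fixed = TRUE)[[1L]]
  k <- min_repeat
  lk <- substring(left, 1:(nl - k + 1L), k:nl)
  rk <- substring(right, 1:(nr - k + 1L), k:nr)
  l_index <- split(seq_len(nl - k + 1L), lk)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (j in seq_len(nr - k + 1L)) {
    starts <- l_index[[rk[j]]]
    if (is.null(starts)) next
    for (i in starts) {
      # extend the seed match maximally left and right within the flanks
      a <- i; b <- j
      while (a > 1L && b > 1L && lv[a - 1L] == rv[b - 1L]) {
        a <- a - 1L; b <- b - 1L
      }
      ea <- i + k - 1L; eb <- j + k - 1L
      while (ea < nl && eb < nr && lv[ea + 1L] == rv[eb + 1L]) {
        ea <- ea + 1L; eb <- eb + 1L
      }
      key <- paste(a, b, ea - a + 1L, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <-
        c(a = a, b = b, len = ea - a + 1L)
    }
  }
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(
    repeat_seq = substring(left, m[, "a"], m[, "a"] + m[, "len"] - 1L),
    length = as.integer(m[, "len"]),
    left_start = as.integer(l0 + m[, "a"] - 1L),
    left_end = as.integer(l0 + m[, "a"] - 1L + m[, "len"]),
    right_start = as.integer(span[2L] + m[, "b"] - 1L),
    right_end = as.integer(span[2L] + m[, "b"] - 1L + m[, "len"]),
    stringsAsFactors = FALSE)
  g <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  .overlaps <- function(s, e, gs, ge) s < ge & gs < e
  context <- character(nrow(out))
  for (r in seq_len(nrow(out))) {
    trna <- any(g$is_trna &
                  (.overlaps(out$left_start[r], out$left_end[r], g$start, g$end) |
                   .overlaps(out$right_start[r], out$right_end[r], g$start, g$end)))
    if (trna) { context[r] <- "tRNA"; next }
    enc <- g$is_integrase &
      .overlaps(out$left_end[r], out$right_start[r], g$start, g$end)
    copy_inside <- any(g$is_integrase &
      ((out$left_start[r] >= g$start & out$left_end[r] <= g$end) |
       (out$right_start[r] >= g$start & out$right_end[r] <= g$end)))
    context[r] <- if (any(enc) && !copy_inside) "non_integrase" else "plain"
  }
  out$context <- context
  out$distance <- (span[1L] - out$left_end) + (out$right_start - span[2L])
  out <- out[order(-out$length, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Type a detection into a completeness class
#'
#' Circular contigs are complete genomes (`"circular"`, span = whole contig);
#' integrated predictions with an att repeat in a tRNA or non-integrase
#' context are `"canonical_att"`, with a plain repeat `"noncanonical_att"`
#' (span extended to the outer bounds of the best att pair); predictions
#' without identifiable ends are `"fuzzy"` (span = gene window span). A
#' prediction with >= 2 pI genes is flagged tandem.
#'
#' @param genome An `annotated_genome`.
#' @param contig_id Contig of the prediction.
#' @param window Gene index pair `c(i, j)` from [scan_windows()].
#' @param att_hits att table from [find_att_sites()] (may be empty/`NULL`).
#' @param pi_gene_id Marker gene identifier.
#' @param pi_count Number of pI genes in the window.
#' @param score Window score.
#' @param prediction_id,genome_id Identifiers carried into the record.
#' @return A one-row `inovirus_predictions` table.
#' @export
classify_prediction <- function(genome, contig_id, window, att_hits,
                                pi_gene_id, pi_count = 1L, score = NA_real_,
                                prediction_id = paste0(contig_id, "_pred"),
                                genome_id = NA_character_) {
  g <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  gspan <- c(g$start[window[1L]], g$end[window[2L]])
  att <- NULL
  if (!is.null(att_hits) && nrow(att_hits)) att <- att_hits[1L, , drop = FALSE]
  circular <- unname(genome$topology[[contig_id]]) == "circular"
  if (circular) {
    completeness <- "circular"
    span <- c(0L, nchar(genome$contigs[[contig_id]]))
    att <- NULL
  } else if (!is.null(att)) {
    completeness <- if (att$context %in% c("tRNA", "non_integrase"))
      "canonical_att" else "noncanonical_att"
    span <- c(att$left_start, att$right_end)
  } else {
    completeness <- "fuzzy"
    span <- gspan
  }
  .as_predictions(data.frame(
    prediction_id = prediction_id, genome_id = genome_id,
    contig_id = contig_id, start = span[1L], end = span[2L],
    gene_start = window[1L], gene_end = window[2L],
    pi_gene_id = pi_gene_id, window_score = score,
    completeness = completeness, tandem = pi_count >= 2L,
    att_seq = if (is.null(att)) NA_character_ else att$repeat_seq,
    att_left_start = if (is.null(att)) NA_integer_ else att$left_start,
    att_left_end = if (is.null(att)) NA_integer_ else att$left_end,
    att_right_start = if (is.null(att)) NA_integer_ else att$right_start,
    att_right_end = if (is.null(att)) NA_integer_ else att$right_end,
    att_context = if (is.null(att)) NA_character_ else att$context,
    stringsAsFactors = FALSE))
}

# Boundary refinement: the window returned by the classifier can over-reach
# the provirus by a gene or two, swallowing an att copy into the span where
# the flank search cannot see it. Integration duplicates the repeat at the
# *true* boundary, so the att pair is searched over nested candidate windows
# (the scored window shrunk by up to `max_shrink` genes per side, never past
# the pI gene) and the best pair across all of them — longest repeat, then
# closest to its span — is kept, tagged with the window it came from.
.refine_att <- function(genome, contig, cg, window, flank_bp, pi_idx,
                        max_shrink = 2L) {
  best <- NULL
  for (di in 0:max_shrink) for (dj in 0:max_shrink) {
    i <- window[1L] + di; j <- window[2L] - dj
    if (i > min(pi_idx) || j < max(pi_idx) || i > j) next
    span <- c(cg$start[i], cg$end[j])
    att <- find_att_sites(genome, contig, span, flank_bp = flank_bp)
    if (nrow(att) == 0L) next
    cand <- att[1L, , drop = FALSE]
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$distance < best$distance))
      best <- cand
  }
  best
}

#' Detect inovirus regions in one annotated genome
#'
#' The full per-genome pipeline: scan translated genes against the marker
#' models, filter hits at the profile thresholds, maximize the window score
#' around each retained pI gene, merge overlapping windows (multiple pI genes
#' in one region = tandem), search the flanks for att repeats, and type each
#' prediction.
#'
#' @param genome An `annotated_genome`.
#' @param classifier An `inovirus_classifier`.
#' @param models Marker model(s) for [scan_markers()].
#' @param known_pc_hits See [extract_features()].
#' @param genome_id Identifier stamped on predictions.
#' @param hit_mode Filter mode for [filter_marker_hits()].
#' @param flank_bp att search distance.
#' @param ... Passed to [scan_windows()].
#' @return An `inovirus_predictions` table (possibly empty).
#' @export
detect_inoviruses <- function(genome, classifier, models,
                              known_pc_hits = NULL,
                              genome_id = NA_character_,
                              hit_mode = "profile", flank_bp = 20000L, ...) {
  hits <- filter_marker_hits(scan_markers(genome, models), mode = hit_mode)
  if (nrow(hits) == 0L) return(empty_predictions())
  g <- genome$genes
  preds <- list()
  for (contig in unique(g$contig_id[g$gene_id %in% hits$gene_id])) {
    cg <- g[g$contig_id == contig, , drop = FALSE]
    pi_idx <- sort(unique(match(
      hits$gene_id[hits$gene_id %in% cg$gene_id], cg$gene_id)))
    wins <- list()
    for (p in pi_idx) {
      w <- scan_windows(genome, contig, p, classifier,
                        known_pc_hits = known_pc_hits, ...)
      if (!is.null(w)) wins[[length(wins) + 1L]] <-
          list(window = w$window, score = w$score, pi = p)
    }
    if (length(wins) == 0L) next
    # merge overlapping windows: a region with several pI genes is one
    # (tandem) prediction
    ord <- order(vapply(wins, function(w) w$window[1L], integer(1)))
    wins <- wins[ord]
    merged <- list(wins[[1L]])
    merged[[1L]]$pis <- merged[[1L]]$pi
    if (length(wins) > 1L) for (w in wins[-1L]) {
      last <- merged[[length(merged)]]
      if (w$window[1L] <= last$window[2L]) {
        last$window[2L] <- max(last$window[2L], w$window[2L])
        last$score <- max(last$score, w$score)
        last$pis <- c(last$pis, w$pi)
        merged[[length(merged)]] <- last
      } else {
        w$pis <- w$pi
        merged[[length(merged) + 1L]] <- w
      }
    }
    for (m in seq_along(merged)) {
      w <- merged[[m]]
      gspan <- c(cg$start[w$window[1L]], cg$end[w$window[2L]])
      att <- if (genome$topology[[contig]] == "circular") NULL
             else .refine_att(genome, contig, cg, w$window, flank_bp,
                              pi_idx = w$pis)
      # count pI genes inside the merged window (marker hits within range)
      n_pi <- sum(pi_idx >= w$window[1L] & pi_idx <= w$window[2L])
      preds[[length(preds) + 1L]] <- classify_prediction(
        genome, contig, w$window, att,
        pi_gene_id = cg$gene_id[w$pi], pi_count = n_pi, score = w$score,
        prediction_id = paste0(contig, "_pred", m), genome_id = genome_id)
    }
  }
  if (length(preds) == 0L) return(empty_predictions())
  .as_predictions(do.call(rbind, preds))
}
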