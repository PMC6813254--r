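# Sequence-only protein feature heuristics: transmembrane domains by
# Kyte-Doolittle hydropathy, a tripartite signal-peptide rule, and the
# short/1-2-TMD inovirus structural-candidate test. These are deliberately
# simple, published-scale heuristics; parsers for external predictor output
# can be plugged in wherever span counts are consumed.

#' Kyte-Doolittle hydropathy values
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
kd_hydropathy <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.residue_hydropathy <- function(protein) {
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  h <- unname(kd_hydropathy[res])
  h[is.na(h)] <- 0  # unknown residues are hydropathy-neutral
  h
}

#' Predict transmembrane domains from windowed hydropathy
#'
#' Slides a `window`-residue window over the sequence and keeps windows whose
#' mean Kyte-Doolittle hydropathy is at least `cutoff`; the union of
#' qualifying windows, merged over overlaps, gives the TMD spans. The default
#' window (19) and cutoff (1.6) are the classic settings for membrane-spanning
#' segment detection. Deterministic; proteins shorter than the window yield no
#' spans.
#'
#' @param protein Amino-acid string.
#' @param window Window length in residues.
#' @param cutoff Minimum mean hydropathy per window.
#' @return `data.frame` with `start`, `end` (0-based half-open residue
#'   coordinates) and `mean_hydropathy` over the span; zero rows if none.
#' @export
predict_tmds <- function(protein, window = 19L, cutoff = 1.6) {
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = double())
  n <- nchar(protein)
  if (n < window) return(empty)
  h <- .residue_hydropathy(protein)
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  q <- which(means >= cutoff)          # qualifying window starts (1-based)
  if (length(q) == 0L) return(empty)
  covered <- rep(FALSE, n)
  for (s in q) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = starts[keep] - 1L,
    end = ends[keep],
    mean_hydropathy = vapply(keep, function(i) {
      mean(h[starts[i]:ends[i]])
    }, double(1)))
}

.basic_residues <- c("K", "R")
# h-region set excludes A/G/S so that the small cleavage-site residues can
# never be absorbed into the hydrophobic stretch
.sp_hydrophobic_residues <- c("C", "F", "I", "L", "M", "V", "W")
.small_residues <- c("A", "G", "S")

#' Strip an N-terminal signal peptide (tripartite heuristic)
#'
#' Looks, within the first 35 residues, for a basic residue (n-region)
#' followed by a hydrophobic stretch of at least 7 residues (h-region) ending
#' before position 35, and cleaves after the first small residue (A/G/S)
#' following that stretch (c-region cleavage site). Sequences not matching the
#' pattern are returned unchanged.
#'
#' @param protein Amino-acid string.
#' @return `list(mature = <string>, stripped = <logical>)`.
#' @export
strip_signal_peptide <- function(protein) {
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  n <- length(res)
  unchanged <- list(mature = protein, stripped = FALSE)
  if (n < 10L) return(unchanged)
  basics <- which(res[seq_len(min(35L, n))] %in% .basic_residues)
  if (length(basics) == 0L) return(unchanged)
  hydro <- res %in% .sp_hydrophobic_residues
  for (b in basics) {
    # first hydrophobic run of >= 7 starting after the basic residue and
    # ending before position 35
    i <- b + 1L
    while (i <= min(34L, n)) {
      if (hydro[i]) {
        j <- i
        while (j < n && hydro[j + 1L]) j <- j + 1L
        if (j - i + 1L >= 7L && j < 35L) {
          k <- j + 1L
          while (k <= n && !(res[k] %in% .small_residues)) k <- k + 1L
          if (k <= n) {
            return(list(mature = substr(protein, k + 1L, n), stripped = TRUE))
          }
          return(unchanged)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  unchanged
}

#' Is a protein a candidate inovirus structural protein?
#'
#' After in-silico signal-peptide removal, a candidate structural protein is
#' 30-90 amino acids long and carries 1 or 2 predicted TMDs. The stricter
#' single-TMD variant (the dominant case among known inovirus coat proteins)
#' is available via `tmd_counts = 1`.
#'
#' @param protein Amino-acid string (`NA` returns `FALSE`).
#' @param min_len,max_len Mature-length bounds (inclusive).
#' @param tmd_counts Admissible TMD counts (default `c(1, 2)`).
#' @return Logical scalar.
#' @export
is_candidate_structural <- function(protein, min_len = 30L, max_len = 90L,
                                    tmd_counts = c(1L, 2L)) {
  if (is.na(protein) || !nzchar(protein)) return(FALSE)
  mature <- strip_signal_peptide(protein)$mature
  len <- nchar(mature)
  if (len < min_len || len > max_len) return(FALSE)
  nrow(predict_tmds(mature)) %in% tmd_counts
}
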