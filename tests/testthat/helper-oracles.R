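# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use naive algorithms (exhaustive loops,
# diagonal run-length scans) so they share no code path with the
# implementations they check.

# exhaustive ungapped PSSM placement: loop over offsets, sum column scores
oracle_pssm_scan <- function(scores, protein) {
  aa <- rownames(scores)
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  L <- ncol(scores); n <- length(res)
  if (n < L) return(NULL)
  best <- -Inf; at <- NA_integer_
  for (o in 1:(n - L + 1L)) {
    s <- 0
    for (j in 1:L) {
      r <- match(res[o + j - 1L], aa)
      s <- s + if (is.na(r)) 0 else scores[r, j]
    }
    if (s > best) { best <- s; at <- o }
  }
  list(score = unname(best), offset = at)
}

# all maximal equal-substring pairs (>= k) between two strings, via
# per-diagonal vectorized comparison + run-length encoding. Diagonals are
# pre-selected by exact base-4 k-mer codes (no hashing collisions): every
# equal substring of length >= k contains a shared k-mer on its diagonal, so
# the pre-selection is lossless and only the per-diagonal run scan decides
# what is reported.
oracle_direct_repeats <- function(left, right, k = 10L) {
  lv <- strsplit(left, "", fixed = TRUE)[[1L]]
  rv <- strsplit(right, "", fixed = TRUE)[[1L]]
  nl <- length(lv); nr <- length(rv)
  kmer_codes <- function(v) {
    x <- match(v, c("A", "C", "G", "T")) - 1
    n <- length(x)
    if (n < k) return(numeric(0))
    code <- numeric(n - k + 1L)
    for (j in seq_len(k)) code <- code + x[j:(n - k + j)] * 4^(k - j)
    code
  }
  cl <- kmer_codes(lv); cr <- kmer_codes(rv)
  shared <- intersect(cl, cr)
  diags <- sort(unique(unlist(lapply(shared, function(v)
    as.vector(outer(which(cl == v), which(cr == v), `-`))))))
  rows <- list()
  for (d in diags) {
    i <- max(1L, d + 1L):min(nl, nr + d)
    eq <- lv[i] == rv[i - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (w in which(r$values & r$lengths >= k)) {
      a <- i[starts[w]]
      rows[[length(rows) + 1L]] <-
        c(left_start = a, right_start = a - d, length = r$lengths[w])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(left_start = integer(), right_start = integer(),
                      length = integer()))
  out <- unique(as.data.frame(do.call(rbind, rows)))
  out[order(out$left_start, out$right_start), , drop = FALSE]
}

# exhaustive <=max_mm Hamming placements of spacer on target (one strand)
oracle_hamming <- function(spacer, target, max_mm = 1L) {
  sv <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  tv <- strsplit(target, "", fixed = TRUE)[[1L]]
  m <- length(sv); n <- length(tv)
  rows <- list()
  if (n >= m) for (o in 1:(n - m + 1L)) {
    mm <- sum(tv[o:(o + m - 1L)] != sv)
    if (mm <= max_mm)
      rows[[length(rows) + 1L]] <- c(start = o - 1L, mismatches = mm)
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), mismatches = integer()))
  as.data.frame(do.call(rbind, rows))
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# exhaustive window enumeration around a pI gene with the documented
# tie-breaking (smallest interval, then leftmost)
oracle_scan <- function(genome, contig, p, scorer, max_window = 30L) {
  g <- genome$genes[genome$genes$contig_id == contig, , drop = FALSE]
  n <- nrow(g)
  best <- NULL
  for (i in 1:p) for (j in p:n) {
    if (j - i + 1L > max_window) next
    fv <- extract_features(genome, contig, c(i, j))
    s <- drop(scorer(matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))))
    better <- is.null(best) || s > best$score ||
      (s == best$score && (j - i < best$size ||
                             (j - i == best$size && i < best$i)))
    if (better) best <- list(score = s, i = i, j = j, size = j - i)
  }
  best
}

# random annotated genome used as a mock landscape for window-scan tests;
# translations = FALSE keeps feature extraction cheap for bulk property runs
make_random_genome <- function(n_genes, seed, contig_len_pad = 500L,
                               translations = TRUE) {
  set.seed(seed)
  lens <- 3L * sample(40:400, n_genes, replace = TRUE)
  gaps <- sample(0:120, n_genes, replace = TRUE)
  starts <- cumsum(gaps + c(0L, lens[-n_genes]))
  ends <- starts + lens
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:n_genes), contig_id = "c1",
    start = starts, end = ends,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    translation = if (translations) vapply(lens / 3 - 1, function(k)
      paste(sample(c("D", "E", "K", "N", "Q", "S", "T", "G"), k,
                   replace = TRUE), collapse = ""), character(1))
      else NA_character_,
    annotation = ifelse(runif(n_genes) < 0.5, "hypothetical-like", ""),
    stringsAsFactors = FALSE)
  contig <- paste(sample(c("A", "C", "G", "T"), ends[n_genes] + contig_len_pad,
                         replace = TRUE), collapse = "")
  annotated_genome(c(c1 = contig), genes)
}

# a deterministic mock scorer: arbitrary smooth function of the features
make_mock_scorer <- function(seed) {
  set.seed(seed)
  w <- runif(10, -1, 1)
  function(feats) {
    x <- as.matrix(feats) %*% w
    (sin(3 * x) + 1) / 2
  }
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# planted block model for the bipartite genome-PC network
block_network <- function(n_blocks, genomes_per, pcs_per, p_in, p_out, seed) {
  set.seed(seed)
  rows <- list()
  truth <- character(0)
  for (b in seq_len(n_blocks)) {
    gs <- sprintf("B%d_g%02d", b, seq_len(genomes_per))
    truth[gs] <- paste0("B", b)
    for (bb in seq_len(n_blocks)) {
      pcs <- sprintf("B%d_pc%02d", bb, seq_len(pcs_per))
      p <- if (b == bb) p_in else p_out
      for (g in gs) {
        hit <- pcs[runif(pcs_per) < p]
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(genome_id = g, pc_id = hit)
      }
    }
  }
  m <- do.call(rbind, rows)
  sizes <- setNames(rep(2L, n_blocks * pcs_per),
                    sprintf("B%d_pc%02d", rep(seq_len(n_blocks), each = pcs_per),
                            rep(seq_len(pcs_per), n_blocks)))
  list(memberships = m, pc_sizes = sizes, truth = truth)
}
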