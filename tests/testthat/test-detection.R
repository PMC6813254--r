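# Feature extraction, classifier training/CV, window maximization, att
# finding and prediction typing.

test_that("single-gene window features match direct computation", {
  genes <- data.frame(gene_id = "g1", contig_id = "c1", start = 100L,
                      end = 400L, strand = "+", translation = NA_character_,
                      annotation = "")
  gen <- annotated_genome(c(c1 = strrep("A", 1000)), genes)
  f <- extract_features(gen, "c1", c(1, 1))
  expect_equal(unname(f["median_gene_len"]), 300)
  expect_equal(unname(f["frac_unannotated"]), 1.0)
  expect_equal(unname(f["strand_coherence"]), 1.0)
  expect_equal(unname(f["window_frac"]), 1 / 30)
  expect_equal(unname(f["gene_density"]), 1 / 0.3)
  expect_equal(unname(f["mean_intergenic_gap"]), 0)
})

test_that("a hand-built 10-gene window matches the spreadsheet oracle", {
  # 5 short unannotated genes, 2 structural candidates, 1 RCR-labelled gene,
  # 2 annotated host-like genes
  structural <- paste0(strrep("D", 10), strrep("L", 21), strrep("E", 19))
  lens <- c(200, 250, 150, 280, 290, 153, 153, 350, 900, 1200)
  anns <- c("", "", "", "", "",
            "", "", "Replication initiation protein (RCR)",
            "DNA polymerase", "ABC transporter")
  strands <- c("+", "+", "+", "+", "+", "+", "+", "+", "-", "+")
  transl <- c(rep(NA_character_, 5), structural, structural, NA, NA, NA)
  starts <- cumsum(c(50, head(lens, -1) + 30))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:10), contig_id = "c1",
                      start = starts, end = starts + lens, strand = strands,
                      translation = transl, annotation = anns)
  gen <- annotated_genome(c(c1 = strrep("A", 6000)), genes)
  pc <- setNames(c(rep(TRUE, 3), rep(FALSE, 7)), genes$gene_id)
  f <- extract_features(gen, "c1", c(1, 10), known_pc_hits = pc)
  span <- max(genes$end) - min(genes$start)
  expect_equal(unname(f["gene_density"]), 10 / (span / 1000))
  expect_equal(unname(f["median_gene_len"]), median(lens))
  expect_equal(unname(f["frac_short_genes"]), mean(lens < 300))
  expect_equal(unname(f["frac_unannotated"]), 0.7)
  expect_equal(unname(f["n_structural"]), 2)
  expect_equal(unname(f["frac_known_pc"]), 0.3)
  expect_equal(unname(f["mean_intergenic_gap"]), 30)
  expect_equal(unname(f["strand_coherence"]), 0.9)
  expect_equal(unname(f["has_replication"]), 1)
  expect_equal(unname(f["window_frac"]), 10 / 30)
  # all-annotated window: no unannotated fraction
  f2 <- extract_features(gen, "c1", c(9, 10))
  expect_equal(unname(f2["frac_unannotated"]), 0)
})

test_that("random forest separates separable toys and is seed-reproducible", {
  set.seed(3)
  x <- rbind(matrix(rnorm(100, 0), 10), matrix(rnorm(100, 6), 10))
  colnames(x) <- sprintf("f%d", 1:10)
  y <- rep(c("background", "inovirus"), each = 10)
  fit <- train_classifier(x, y, seed = 7, ntree = 500)
  s <- predict(fit, x)
  expect_equal(s, rep(c(0, 1), each = 10), tolerance = 0.02)
  fit2 <- train_classifier(x, y, seed = 7, ntree = 500)
  expect_identical(predict(fit2, x), s)     # bit-identical under one seed
  expect_error(train_classifier(x, rep("inovirus", 20), seed = 1),
               "both classes")
})

test_that("identical features with opposite labels score near 0.5", {
  set.seed(11)
  base <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, sprintf("f%d", 1:10)))
  x <- base[rep(1:20, each = 2), ]    # every vector appears with both labels
  y <- rep(c("background", "inovirus"), 20)
  fit <- train_classifier(x, y, seed = 11, ntree = 1000)
  expect_equal(mean(predict(fit, x)), 0.5, tolerance = 0.1)
})

test_that("cross-validation partitions correctly and nails separable data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 8), 20))
  colnames(x) <- sprintf("f%d", 1:10)
  y <- rep(c("background", "inovirus"), each = 20)
  cv <- cross_validate(x, y, k = 10, seed = 5, ntree = 300)
  tab <- table(cv$folds)
  expect_equal(length(tab), 10L)
  expect_lte(diff(range(tab)), 1)           # fold sizes differ by <= 1
  expect_equal(sum(tab), 40L)               # every sample used exactly once
  expect_equal(cv$tpr_at_fpr1, 1.0)         # separable: TPR 1 at FPR 0
  expect_equal(cv$auc, 1.0)
  expect_error(cross_validate(x[1:12, ], y[1:12], k = 10), "at least k")
})

test_that("the pooled-score AUC agrees with an independent ROC implementation", {
  set.seed(6)
  x <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, sprintf("f%d", 1:10)))
  x[, 1] <- x[, 1] + rep(c(0, 1), each = 30)   # weak, noisy signal with ties
  y <- rep(c("background", "inovirus"), each = 30)
  cv <- cross_validate(x, y, k = 5, seed = 8, ntree = 200)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = cv$scores, levels = c("background", "inovirus"),
    direction = "<", quiet = TRUE)))
  expect_equal(cv$auc, ref)
})

test_that("window scan equals exhaustive enumeration with documented tie-breaks", {
  for (case in 1:12) {
    gen <- make_random_genome(sample(5:40, 1), seed = 100 + case)
    n <- nrow(gen$genes)
    p <- sample(n, 1)
    scorer <- make_mock_scorer(case)
    got <- scan_windows(gen, "c1", p, scorer, min_score = -Inf)
    want <- oracle_scan(gen, "c1", p, scorer)
    expect_equal(got$window, c(want$i, want$j))
    expect_equal(got$score, unname(want$score))
  }
})

test_that("window scan respects the score cutoff and contig boundaries", {
  gen <- make_random_genome(20, seed = 9)
  low <- function(feats) rep(0.89, nrow(feats))
  expect_null(scan_windows(gen, "c1", 5, low))            # all scores <= 0.9
  exact <- function(feats) rep(0.9, nrow(feats))
  expect_null(scan_windows(gen, "c1", 5, exact))          # 0.9 is not > 0.9
  eps <- function(feats) rep(0.9 + 1e-9, nrow(feats))
  w <- scan_windows(gen, "c1", 5, eps)
  expect_equal(w$window, c(5, 5))     # tie-break: smallest, then leftmost
  w1 <- scan_windows(gen, "c1", 1, eps)
  expect_gte(w1$window[1], 1)                              # truncated left
})

test_that("att finding equals the diagonal brute-force oracle", {
  set.seed(123)
  nt <- c("A", "C", "G", "T")
  for (case in 1:20) {
    left <- paste(sample(nt, 1500, TRUE), collapse = "")
    right <- paste(sample(nt, 1500, TRUE), collapse = "")
    # plant a repeat of length 9-20
    len <- sample(9:20, 1)
    rep_seq <- paste(sample(nt, len, TRUE), collapse = "")
    li <- sample(400:900, 1); ri <- sample(400:900, 1)
    substr(left, li, li + len - 1) <- rep_seq
    substr(right, ri, ri + len - 1) <- rep_seq
    span_seq <- paste(sample(nt, 800, TRUE), collapse = "")
    contig <- paste0(left, span_seq, right)
    gen <- annotated_genome(c(c1 = contig))
    got <- find_att_sites(gen, "c1", c(1500L, 2300L), flank_bp = 1500L)
    want <- oracle_direct_repeats(left, right, k = 10L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      got_o <- got[order(got$left_start, got$right_start), ]
      expect_equal(got_o$left_start, want$left_start - 1L)   # 0-based
      expect_equal(got_o$right_start, 2300L + want$right_start - 1L)
      expect_equal(got_o$length, want$length)
      expect_true(all(got$length >= 10L))
    }
  }
})

test_that("a 9-bp repeat that cannot extend is never reported", {
  # repeats bounded by deliberately mismatched bases
  left <- paste0(strrep("A", 500), "C", "GTGTGCGCA", "C", strrep("A", 489))
  right <- paste0(strrep("T", 300), "G", "GTGTGCGCA", "G", strrep("T", 689))
  contig <- paste0(left, strrep("A", 200), right)
  gen <- annotated_genome(c(c1 = contig))
  got <- find_att_sites(gen, "c1", c(1000L, 1200L), flank_bp = 1000L)
  expect_equal(nrow(got), 0L)
})

test_that("att context classification distinguishes tRNA, integrase and plain", {
  set.seed(8)
  nt <- c("A", "C", "G", "T")
  rep_seq <- "ACGTTGCAACGTGG"  # 14 bp
  left <- paste(sample(nt, 1000, TRUE), collapse = "")
  right <- paste(sample(nt, 1000, TRUE), collapse = "")
  substr(left, 801, 814) <- rep_seq
  substr(right, 101, 114) <- rep_seq
  mid <- paste(sample(nt, 2000, TRUE), collapse = "")
  contig <- paste0(left, mid, right)
  span <- c(1000L, 3000L)
  base_genes <- data.frame(
    gene_id = "int1", contig_id = "c1", start = 1500L, end = 2400L,
    strand = "+", translation = NA_character_, annotation = "phage integrase")
  # integrase inside the enclosed region, copies outside it -> non_integrase
  gen_int <- annotated_genome(c(c1 = contig), base_genes)
  got <- find_att_sites(gen_int, "c1", span, flank_bp = 1000L)
  expect_equal(got$context[1], "non_integrase")
  # a tRNA overlapping the left copy wins
  trna <- data.frame(gene_id = "t1", contig_id = "c1", start = 780L,
                     end = 840L, strand = "+", translation = NA_character_,
                     annotation = "tRNA-Met")
  gen_trna <- annotated_genome(c(c1 = contig), rbind(base_genes, trna))
  got2 <- find_att_sites(gen_trna, "c1", span, flank_bp = 1000L)
  expect_equal(got2$context[1], "tRNA")
  # no genes at all -> plain
  gen_plain <- annotated_genome(c(c1 = contig))
  got3 <- find_att_sites(gen_plain, "c1", span, flank_bp = 1000L)
  expect_equal(got3$context[1], "plain")
})

test_that("prediction typing follows topology and att context", {
  set.seed(21)
  fx <- generate_fixture(simulation_config(
    seed = 13, n_genomes = 3, n_inovirus = 3, n_plasmid = 0, n_caudo = 0,
    host_genes = 20, frac_circular = 0.34, trna_fraction = 1, n_spacers = 0))
  circ <- fx$truth[fx$truth$circular, ][1, ]
  gen <- fx$genomes[[circ$genome_id]]
  p <- classify_prediction(gen, circ$contig_id, c(1, 3), NULL, "g1")
  expect_equal(p$completeness, "circular")
  expect_equal(c(p$start, p$end), c(0L, nchar(gen$contigs[[circ$contig_id]])))
  intg <- fx$truth[!fx$truth$circular, ][1, ]
  gen2 <- fx$genomes[[intg$genome_id]]
  g2 <- gen2$genes[gen2$genes$contig_id == intg$contig_id, ]
  win <- range(which(g2$start >= intg$start & g2$end <= intg$end))
  att <- find_att_sites(gen2, intg$contig_id,
                        c(g2$start[win[1]], g2$end[win[2]]), flank_bp = 2500L)
  p2 <- classify_prediction(gen2, intg$contig_id, win, att, g2$gene_id[win[1]])
  expect_equal(p2$completeness, "canonical_att")     # tRNA-context repeat
  expect_false(is.na(p2$att_seq))
  # canonical/noncanonical always store an att site; fuzzy never does
  p3 <- classify_prediction(gen2, intg$contig_id, win, NULL, "x")
  expect_equal(p3$completeness, "fuzzy")
  expect_true(is.na(p3$att_seq))
  # tandem flag
  p4 <- classify_prediction(gen2, intg$contig_id, win, att, "x", pi_count = 2L)
  expect_true(p4$tandem)
})
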