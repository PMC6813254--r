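# The synthetic-data generator: determinism, planted structure, and the
# truth-scoring harness.

small_cfg <- function(seed = 5, n_spacers = 8, ...) {
  simulation_config(seed = seed, n_genomes = 6, n_inovirus = 3, n_plasmid = 2,
                    n_caudo = 1, host_genes = 20, n_spacers = n_spacers, ...)
}

test_that("fixtures are byte-identical under a fixed seed", {
  f1 <- generate_fixture(small_cfg())
  f2 <- generate_fixture(small_cfg())
  expect_identical(f1, f2)
  f3 <- generate_fixture(small_cfg(seed = 6))
  expect_false(identical(f1$genomes[[1]]$contigs, f3$genomes[[1]]$contigs))
})

test_that("truth spans follow the configured composition", {
  cfg <- simulation_config(seed = 2, n_genomes = 1, n_inovirus = 1,
                           n_plasmid = 0, n_caudo = 0, host_genes = 15,
                           frac_circular = 0, n_spacers = 0)
  fx <- generate_fixture(cfg)
  expect_equal(nrow(fx$truth), 1L)
  expect_equal(fx$truth$type, "inovirus")
  gen <- fx$genomes[[fx$truth$genome_id]]
  expect_lte(fx$truth$end, nchar(gen$contigs[[fx$truth$contig_id]]))
})

test_that("planted regions satisfy the detector's feature assumptions", {
  fx <- generate_fixture(small_cfg(seed = 9))
  for (r in which(fx$truth$type == "inovirus")) {
    t <- fx$truth[r, ]
    g <- fx$genomes[[t$genome_id]]$genes
    inside <- g[g$contig_id == t$contig_id & g$start >= t$start &
                  g$end <= t$end & !is.na(g$translation), ]
    # pI motif detectable
    hits <- do.call(rbind, lapply(inside$translation, function(p)
      score_profile(inovirus_seed_model(), p)))
    expect_gte(max(filter_marker_hits(hits, "profile")$bit_score), 30)
    # at least 2 structural candidates
    expect_gte(sum(vapply(inside$translation, is_candidate_structural,
                          logical(1))), 2)
    # cassette genes shorter than the host background
    host <- g[g$contig_id == t$contig_id &
                (g$end <= t$start | g$start >= t$end), ]
    if (nrow(host))
      expect_lt(median(inside$end - inside$start),
                median(host$end - host$start))
  }
})

test_that("planted att repeats are recovered exactly by the att finder", {
  fx <- generate_fixture(small_cfg(seed = 12, frac_circular = 0))
  for (r in which(fx$truth$type == "inovirus")) {
    t <- fx$truth[r, ]
    gen <- fx$genomes[[t$genome_id]]
    att <- find_att_sites(gen, t$contig_id,
                          c(t$att_left_end, t$att_right_start),
                          flank_bp = 2500L)
    expect_gte(nrow(att), 1L)
    expect_equal(att$left_end[1], t$att_left_end)
    expect_equal(att$right_start[1], t$att_right_start)
    expect_gte(att$length[1], fx$config$att_len)
  }
})

test_that("species replicates diverge by the configured exact amount", {
  set.seed(1)
  parent <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  child <- mutate_sequence(parent, 0.05)
  r <- compute_ani(parent, child)
  expect_equal(r$ani, 95, tolerance = 0.5 / 95)
  expect_gte(r$af, 0.99)
  # and inside the generator: same-species plantings stay above 95% ANI
  fx <- generate_fixture(small_cfg(seed = 21, n_species = 2))
  ino <- fx$truth[fx$truth$type == "inovirus", ]
  by_sp <- split(seq_len(nrow(ino)), ino$species_id)
  for (idx in by_sp[lengths(by_sp) > 1]) {
    s1 <- ino[idx[1], ]; s2 <- ino[idx[2], ]
    a <- substr(fx$genomes[[s1$genome_id]]$contigs[[s1$contig_id]],
                s1$start + 1, s1$end)
    b <- substr(fx$genomes[[s2$genome_id]]$contigs[[s2$contig_id]],
                s2$start + 1, s2$end)
    expect_gte(compute_ani(a, b)$ani, 95)
  }
})

test_that("spacers trace back to their source provirus", {
  fx <- generate_fixture(small_cfg(seed = 30))
  expect_equal(length(fx$spacers), 8L)
  info <- fx$spacer_info
  for (i in seq_len(nrow(info))) {
    t <- fx$truth[fx$truth$truth_id == info$truth_id[i], ]
    target <- substr(fx$genomes[[t$genome_id]]$contigs[[t$contig_id]],
                     t$start + 1, t$end)
    m <- match_spacers(fx$spacers[info$spacer_id[i]], c(t = target),
                       max_mm = 2L)
    expect_gte(nrow(m), 1L)
    expect_equal(min(m$mismatches), info$n_mut[i])
  }
})

test_that("truth scoring implements the reciprocal-overlap conventions", {
  truth <- data.frame(truth_id = "t1", genome_id = "g1", contig_id = "c1",
                      start = 1000L, end = 5000L, type = "inovirus",
                      circular = FALSE, att_left_start = 1000L,
                      att_left_end = 1014L, att_right_start = 4986L,
                      att_right_end = 5000L, species_id = "sp", n_pi = 1L)
  perfect <- empty_predictions()
  perfect <- rbind(perfect, data.frame(
    prediction_id = "p1", genome_id = "g1", contig_id = "c1",
    start = 1000L, end = 5000L, gene_start = 1L, gene_end = 5L,
    pi_gene_id = "g", window_score = 0.99, completeness = "canonical_att",
    tandem = FALSE, att_seq = "X", att_left_start = 1000L,
    att_left_end = 1014L, att_right_start = 4986L, att_right_end = 5000L,
    att_context = "tRNA"))
  s <- score_against_truth(perfect, truth)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)
  expect_equal(s$boundary_error$mean, 0)
  # empty predictions: recall 0, precision 1 with the zero-call flag
  s0 <- score_against_truth(empty_predictions(), truth)
  expect_equal(s0$recall, 0)
  expect_equal(s0$precision, 1)
  expect_true(s0$zero_call)
  # a 40%-overlap shifted span does not match at threshold 0.5
  shifted <- perfect
  shifted$start <- 3400L; shifted$end <- 7400L   # overlap 1600/4000 = 0.4
  s40 <- score_against_truth(shifted, truth)
  expect_equal(s40$recall, 0)
  expect_equal(s40$precision, 0)
})

test_that("fixture files land on disk in readable formats", {
  fx <- generate_fixture(small_cfg(seed = 40, n_spacers = 3))
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "truth.bed")))
  sp <- Biostrings::readDNAStringSet(file.path(dir, "spacers.fasta"))
  expect_equal(length(sp), 3L)
  gid <- names(fx$genomes)[1]
  re <- load_annotated_genome(file.path(dir, paste0(gid, ".fna")),
                              file.path(dir, paste0(gid, "_genes.tsv")))
  expect_equal(re$contigs, fx$genomes[[gid]]$contigs)
})
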