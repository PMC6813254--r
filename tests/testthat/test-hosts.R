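# CRISPR spacer matching, cas-context filtering, self-targeting,
# Caudovirales co-infection and prevalence.

rand_dna2 <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

test_that("spacer matching reports exact and 1-mismatch hits on both strands", {
  set.seed(1)
  target <- rand_dna2(300)
  sp0 <- substr(target, 50, 81)                        # exact, forward
  v <- strsplit(substr(target, 120, 151), "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  sp1 <- revcomp(paste(v, collapse = ""))              # 1 mismatch, reverse
  v2 <- strsplit(substr(target, 200, 231), "")[[1]]
  v2[c(3, 20)] <- vapply(v2[c(3, 20)], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  sp2 <- paste(v2, collapse = "")                      # 2 mismatches
  m <- match_spacers(c(s0 = sp0, s1 = sp1, s2 = sp2), c(t = target))
  m0 <- m[m$spacer_id == "s0", ]
  expect_true(any(m0$start == 49 & m0$mismatches == 0 & m0$strand == "+"))
  m1 <- m[m$spacer_id == "s1", ]
  expect_true(any(m1$start == 119 & m1$mismatches == 1 & m1$strand == "-"))
  expect_false("s2" %in% m$spacer_id)                  # best is 2 mismatches
})

test_that("spacer matching equals the exhaustive Hamming oracle", {
  set.seed(2)
  for (case in 1:60) {
    target <- rand_dna2(150)
    spacer <- rand_dna2(30)
    if (case %% 3 == 0) {  # plant with 0-2 mismatches, random strand
      at <- sample(120, 1)
      pl <- substr(target, at, at + 29)
      pl <- mutate_sequence(pl, sample(0:2, 1) / 30)
      spacer <- if (runif(1) < 0.5) pl else revcomp(pl)
    }
    got <- match_spacers(c(s = spacer), c(t = target))
    fwd <- oracle_hamming(spacer, target)
    rev <- oracle_hamming(revcomp(spacer), target)
    expect_equal(sort(got$start[got$strand == "+"]), sort(fwd$start))
    expect_equal(sort(got$start[got$strand == "-"]), sort(rev$start))
    expect_equal(sum(got$mismatches[got$strand == "+"]), sum(fwd$mismatches))
  }
})

test_that("matching is strand-symmetric", {
  set.seed(3)
  target <- rand_dna2(200)
  spacer <- substr(target, 40, 70)
  a <- match_spacers(c(s = spacer), c(t = target))
  b <- match_spacers(c(s = revcomp(spacer)), c(t = revcomp(target)))
  # a hit at [start, end) on + maps to [n - end, n - start) on the
  # reverse-complemented target
  n <- nchar(target)
  expect_setequal(paste(n - a$end, n - a$start, a$mismatches),
                  paste(b$start, b$end, b$mismatches))
})

test_that("cas context is required within 10 kb for host-derived spacers", {
  mk_host <- function(cas_at) {
    genes <- data.frame(
      gene_id = c("h1", "cas"), contig_id = "c1",
      start = c(100L, cas_at), end = c(400L, cas_at + 900L), strand = "+",
      translation = NA_character_,
      annotation = c("DNA polymerase", "cas9 endonuclease"))
    annotated_genome(c(c1 = strrep("A", 60000)), genes)
  }
  matches <- data.frame(spacer_id = "sp1", target_id = "pred1", strand = "+",
                        start = 0L, end = 32L, mismatches = 0L, best = TRUE)
  loci <- data.frame(spacer_id = "sp1", genome_id = "host1",
                     start = 20000L, end = 20032L)
  near <- require_cas_context(matches, loci, list(host1 = mk_host(28000L)))
  expect_equal(nrow(near), 1L)                       # cas 8 kb away: kept
  expect_true(near$cas_context)
  far <- require_cas_context(matches, loci, list(host1 = mk_host(32100L)))
  expect_equal(nrow(far), 0L)                        # cas ~12 kb away: removed
  bare <- annotated_genome(c(c1 = strrep("A", 60000)))
  none <- require_cas_context(matches, loci, list(host1 = bare))
  expect_equal(nrow(none), 0L)                       # no annotation: removed
  meta <- require_cas_context(
    matches, data.frame(spacer_id = "sp1", genome_id = NA_character_,
                        start = NA_integer_, end = NA_integer_),
    list())
  expect_equal(nrow(meta), 1L)                       # no coordinates: kept
  expect_false(meta$cas_context)
})

test_that("self-targeting means spacer and provirus share a host genome", {
  matches <- data.frame(spacer_id = c("a", "b", "c"),
                        target_id = c("p1", "p2", "p3"),
                        spacer_genome = c("hostX", "hostY", "hostZ"),
                        stringsAsFactors = FALSE)
  hosts <- c(p1 = "hostX", p2 = "hostQ", p3 = NA_character_)
  out <- detect_self_targeting(matches, hosts)
  expect_equal(out$self_targeting, c(TRUE, FALSE, FALSE))
  expect_equal(out$unresolved, c(FALSE, FALSE, TRUE))
})

test_that("terminase hits flag co-infection at the score threshold", {
  tm <- terminase_seed_models()[[1]]
  consensus <- paste(rownames(tm$scores)[apply(tm$scores, 2, which.max)],
                     collapse = "")
  mutate_cols <- function(p, m) {
    v <- strsplit(p, "")[[1]]
    aa <- rownames(tm$scores)
    for (i in seq_len(m)) v[i] <- setdiff(aa, v[i])[1]
    paste(v, collapse = "")
  }
  mk <- function(prot, starts = 1000L) {
    genes <- data.frame(gene_id = sprintf("g%d", seq_along(prot)),
                        contig_id = "c1",
                        start = starts, end = starts + 3L * (nchar(prot) + 1L),
                        strand = "+", translation = prot, annotation = "")
    annotated_genome(c(c1 = strrep("A", 40000)), genes)
  }
  # 14 mutated columns: score 3.39*(28-14) - 14 = 33.5 >= 30 -> flagged
  hi <- detect_caudovirales_coinfection(mk(mutate_cols(consensus, 14)),
                                        terminase_seed_models())
  expect_true(hi$flagged)
  # 15 mutated columns: 29.1 < 30 -> not flagged
  lo <- detect_caudovirales_coinfection(mk(mutate_cols(consensus, 15)),
                                        terminase_seed_models())
  expect_false(lo$flagged)
  # two hits 2 kb apart count once; 8 kb apart count twice
  close_g <- mk(c(consensus, consensus), starts = c(1000L, 3000L))
  expect_equal(detect_caudovirales_coinfection(
    close_g, terminase_seed_models())$n_prophages, 1L)
  far_g <- mk(c(consensus, consensus), starts = c(1000L, 9000L))
  expect_equal(detect_caudovirales_coinfection(
    far_g, terminase_seed_models())$n_prophages, 2L)
})

test_that("prevalence is computed on dereplicated hosts", {
  set.seed(4)
  a <- rand_dna2(4000); b <- rand_dna2(4000)
  hosts <- c(g1 = a, g2 = a, g3 = b)                 # g1/g2 are duplicates
  genus <- c(g1 = "Vibrio", g2 = "Vibrio", g3 = "Nitrosomonas")
  det <- data.frame(genome_id = c("g1", "g1"),
                    species_id = c("sp_001", "sp_002"))
  out <- compute_prevalence(hosts, genus, det)
  prev <- setNames(out$prevalence$prevalence, out$prevalence$genus)
  expect_equal(prev[["Vibrio"]], 1)                  # counted once, 1/1
  expect_equal(prev[["Nitrosomonas"]], 0)
  expect_equal(out$prevalence$n_genomes[out$prevalence$genus == "Vibrio"], 1L)
  expect_equal(out$cooccurrence$n_species, 2L)       # two species, one genome
})
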