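# Reading, writing and the coordinate convention of the annotated-genome
# container and the prediction report.

make_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

test_that("GFF3 loading converts 1-based inclusive to 0-based half-open and flags tRNAs", {
  dir <- withr::local_tempdir()
  set.seed(1)
  fa <- make_fasta(c(c1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                                collapse = "")), file.path(dir, "g.fna"))
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1;product=DNA polymerase",
    "c1\tsrc\ttRNA\t401\t475\t.\t-\t.\tID=t1;product=tRNA-Leu",
    "c1\tsrc\tgene\t601\t900\t.\t+\t.\tID=g2"), gff)
  gen <- load_annotated_genome(fa, gff)
  expect_s3_class(gen, "annotated_genome")
  g <- gen$genes
  expect_equal(g$gene_id, c("g1", "t1", "g2"))  # sorted by start
  expect_equal(g$start, c(0L, 400L, 600L))      # internal = GFF3_start - 1
  expect_equal(g$end, c(300L, 475L, 900L))      # internal = GFF3_end
  expect_equal(g$is_trna, c(FALSE, TRUE, FALSE))
  expect_equal(g$annotation[3], "")             # hypothetical = empty label set
  expect_true(is.na(g$translation[1]))          # kept, flagged untranslated
})

test_that("empty annotation yields a valid zero-gene genome", {
  dir <- withr::local_tempdir()
  fa <- make_fasta(c(c1 = "ACGTACGTACGT"), file.path(dir, "g.fna"))
  tsv <- file.path(dir, "genes.tsv")
  writeLines(paste(c("gene_id", "contig", "start", "end", "strand", "labels",
                     "translation"), collapse = "\t"), tsv)
  gen <- load_annotated_genome(fa, tsv)
  expect_equal(nrow(gen$genes), 0L)
  expect_equal(unname(gen$topology), "linear")
})

test_that("a gene outside its contig is a hard error naming the gene", {
  genes <- data.frame(gene_id = "bad1", contig_id = "c1", start = 10L,
                      end = 200L, strand = "+",
                      translation = NA, annotation = "")
  expect_error(annotated_genome(c(c1 = strrep("A", 100)), genes), "bad1")
  genes2 <- data.frame(gene_id = "bad2", contig_id = "nope", start = 0L,
                       end = 10L, strand = "+",
                       translation = NA, annotation = "")
  expect_error(annotated_genome(c(c1 = strrep("A", 100)), genes2), "bad2")
})

test_that("integrase and tRNA keyword flags are case-insensitive and configurable", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"), contig_id = "c1",
    start = c(0L, 100L, 200L), end = c(90L, 190L, 290L), strand = "+",
    translation = NA_character_,
    annotation = c("Phage_Integrase family", "tRNA-Met", "weird_marker"))
  gen <- annotated_genome(c(c1 = strrep("A", 300)), genes)
  expect_equal(gen$genes$is_integrase, c(TRUE, FALSE, FALSE))
  expect_equal(gen$genes$is_trna, c(FALSE, TRUE, FALSE))
  gen2 <- annotated_genome(c(c1 = strrep("A", 300)), genes,
                           integrase_keywords = "weird_marker")
  expect_equal(gen2$genes$is_integrase, c(FALSE, FALSE, TRUE))
})

test_that("genome write -> load round-trips through both TSV and GFF3", {
  fx <- generate_fixture(simulation_config(
    seed = 11, n_genomes = 2, n_inovirus = 1, n_plasmid = 1, n_caudo = 0,
    host_genes = 15, n_spacers = 0))
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  for (gid in names(fx$genomes)) {
    orig <- fx$genomes[[gid]]
    re_tsv <- load_annotated_genome(
      file.path(dir, paste0(gid, ".fna")),
      file.path(dir, paste0(gid, "_genes.tsv")))
    expect_equal(re_tsv$contigs, orig$contigs)
    expect_equal(re_tsv$genes[, c("gene_id", "start", "end", "strand",
                                  "annotation", "is_trna")],
                 orig$genes[, c("gene_id", "start", "end", "strand",
                                "annotation", "is_trna")])
    expect_equal(re_tsv$genes$translation, orig$genes$translation)
    re_gff <- load_annotated_genome(
      file.path(dir, paste0(gid, ".fna")),
      file.path(dir, paste0(gid, ".gff3")))
    expect_equal(re_gff$genes[, c("gene_id", "start", "end", "strand",
                                  "is_trna")],
                 orig$genes[, c("gene_id", "start", "end", "strand",
                                "is_trna")])
  }
})

test_that("prediction write -> read round-trip is the identity", {
  set.seed(5)
  n <- 10L
  p <- empty_predictions()
  starts <- sort(sample(0:5000, n))
  p <- rbind(p, data.frame(
    prediction_id = sprintf("pred%02d", 1:n),
    genome_id = sprintf("gen%02d", 1:n),
    contig_id = sprintf("c%02d", 1:n),
    start = starts, end = starts + sample(2000:8000, n),
    gene_start = sample(1:5, n, TRUE), gene_end = sample(6:20, n, TRUE),
    pi_gene_id = sprintf("g%02d", 1:n),
    window_score = round(runif(n), 6),
    completeness = sample(c("circular", "canonical_att", "noncanonical_att",
                            "fuzzy"), n, TRUE),
    tandem = sample(c(TRUE, FALSE), n, TRUE),
    att_seq = ifelse(runif(n) < 0.5, strrep("ACGT", 4), NA),
    att_left_start = sample(0:100, n), att_left_end = sample(101:200, n),
    att_right_start = sample(9000:9100, n),
    att_right_end = sample(9101:9200, n),
    att_context = sample(c("tRNA", "plain", NA), n, TRUE),
    stringsAsFactors = FALSE))
  class(p) <- c("inovirus_predictions", "data.frame")
  dir <- withr::local_tempdir()
  write_predictions(p, file.path(dir, "p.gff3"), file.path(dir, "p.tsv"))
  back <- read_predictions(file.path(dir, "p.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(p))
  # GFF3 output is 1-based inclusive
  gff <- readLines(file.path(dir, "p.gff3"))
  row1 <- strsplit(grep("^c", gff, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(row1[4]), p$start[1] + 1L)
  expect_equal(as.integer(row1[5]), p$end[1])
})

test_that("empty prediction lists give valid header-only files", {
  dir <- withr::local_tempdir()
  write_predictions(empty_predictions(),
                    file.path(dir, "e.gff3"), file.path(dir, "e.tsv"))
  expect_equal(readLines(file.path(dir, "e.gff3"))[1], "##gff-version 3")
  back <- read_predictions(file.path(dir, "e.tsv"))
  expect_equal(nrow(back), 0L)
})

test_that("terminal repeats mark circular topology", {
  core <- strrep("ACGTTGCA", 30)
  expect_equal(infer_topology(paste0(core, substr(core, 1, 20))), "circular")
  expect_equal(infer_topology(core), "linear")
})
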