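# Internal coordinates are 0-based half-open everywhere; files on disk
# (FASTA/GFF3/TSV) are 1-based inclusive, the GFF3/GenBank convention.
# The bijection is: internal_start = file_start - 1, internal_end = file_end.

.default_integrase_keywords <- c("integrase", "recombinase", "phage_integrase")
.default_trna_keywords <- c("tRNA")

#' Split semicolon-joined annotation strings into label sets
#'
#' Gene annotation is stored as a single `;`-separated string per gene; an
#' empty string means "hypothetical" (no functional label).
#'
#' @param annotation Character vector of `;`-joined labels.
#' @return A list of character vectors (possibly empty).
#' @export
gene_labels <- function(annotation) {
  out <- strsplit(annotation, ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

# case-insensitive substring match of any keyword against any label
.labels_match <- function(annotation, keywords) {
  if (length(keywords) == 0L) return(rep(FALSE, length(annotation)))
  ann <- tolower(annotation)
  hit <- rep(FALSE, length(ann))
  for (kw in tolower(keywords)) hit <- hit | grepl(kw, ann, fixed = TRUE)
  hit
}

#' Construct an annotated genome
#'
#' The central data container: nucleotide contigs plus an ordered per-contig
#' gene table. Gene coordinates are validated against contig bounds (a gene
#' outside its contig is a hard error naming the offending gene) and genes are
#' sorted by contig then start. tRNA and integrase flags are derived from the
#' annotation labels via configurable case-insensitive keyword lists, so no
#' particular upstream annotation pipeline is mandated.
#'
#' @param contigs Named character vector of nucleotide sequences.
#' @param genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `translation`
#'   (amino-acid string or `NA` for untranslated genes) and `annotation`
#'   (`;`-joined labels, `""` = hypothetical). Optional logical columns
#'   `is_trna` / `is_integrase` are OR-ed with the keyword-derived flags.
#' @param topology Named character vector, `"linear"` or `"circular"` per
#'   contig; defaults to linear. Use [infer_topology()] to detect circularity
#'   from terminal repeats when metadata are absent.
#' @param source_class `"isolate_genome"` or `"metagenome"`; fixed at load.
#' @param integrase_keywords,trna_keywords Keyword lists used to set flags.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(contigs, genes = NULL,
                             topology = NULL,
                             source_class = c("isolate_genome", "metagenome"),
                             integrase_keywords = .default_integrase_keywords,
                             trna_keywords = .default_trna_keywords) {
  source_class <- match.arg(source_class)
  stopifnot(is.character(contigs), length(names(contigs)) == length(contigs))
  contigs <- toupper(contigs)
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), translation = character(),
                        annotation = character(), stringsAsFactors = FALSE)
  }
  req <- c("gene_id", "contig_id", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(genes$translation)) genes$translation <- NA_character_
  if (is.null(genes$annotation)) genes$annotation <- ""
  genes$annotation[is.na(genes$annotation)] <- ""
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)

  if (nrow(genes)) {
    unknown <- !(genes$contig_id %in% names(contigs))
    if (any(unknown))
      stop("gene ", genes$gene_id[which(unknown)[1L]], " references unknown contig ",
           genes$contig_id[which(unknown)[1L]])
    clen <- nchar(contigs)[genes$contig_id]
    bad <- genes$start < 0L | genes$end > clen | genes$start >= genes$end
    if (any(bad))
      stop("gene ", genes$gene_id[which(bad)[1L]],
           " has coordinates outside its contig (or start >= end)")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    kw_trna <- .labels_match(genes$annotation, trna_keywords)
    kw_int <- .labels_match(genes$annotation, integrase_keywords)
    genes$is_trna <- if (is.null(genes$is_trna)) kw_trna else (genes$is_trna | kw_trna)
    genes$is_integrase <-
      if (is.null(genes$is_integrase)) kw_int else (genes$is_integrase | kw_int)
    genes <- genes[order(match(genes$contig_id, names(contigs)), genes$start), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes$is_trna <- logical(0); genes$is_integrase <- logical(0)
  }

  topo <- setNames(rep("linear", length(contigs)), names(contigs))
  if (!is.null(topology)) {
    stopifnot(all(topology %in% c("linear", "circular")))
    topo[names(topology)] <- topology
  }
  structure(list(contigs = contigs, genes = genes, topology = topo,
                 source_class = source_class),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", length(x$contigs), " contig(s), ",
      nrow(x$genes), " gene(s), source: ", x$source_class, "\n", sep = "")
  invisible(x)
}

#' Infer contig topology from exact terminal repeats
#'
#' A contig whose first `min_repeat` (or more) bases exactly equal its last
#' bases is flagged circular, the usual assembler signature of a circular
#' molecule.
#'
#' @param sequence Nucleotide string.
#' @param min_repeat Minimum terminal repeat length (default 20 bp).
#' @return `"circular"` or `"linear"`.
#' @export
infer_topology <- function(sequence, min_repeat = 20L) {
  n <- nchar(sequence)
  if (n < 2L * min_repeat) return("linear")
  if (substr(sequence, 1L, min_repeat) ==
      substr(sequence, n - min_repeat + 1L, n)) "circular" else "linear"
}

#' Load an annotated genome from FASTA plus GFF3 or tabular annotation
#'
#' Coordinates are converted from the 1-based inclusive file convention to the
#' internal 0-based half-open convention. Genes with a missing translation are
#' kept and flagged untranslated (`NA` translation). GFF3 records of type
#' `gene` or `tRNA` become gene records (falling back to `CDS` rows when no
#' `gene` rows exist); functional labels are read from the `product`
#' attribute, translations from a `translation` attribute when present.
#'
#' @param sequence_file Nucleotide FASTA path.
#' @param annotation_file GFF3 (`.gff`/`.gff3`) or tab-separated gene table
#'   with columns `gene_id`, `contig`, `start`, `end`, `strand`, `labels`,
#'   `translation`.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param topology Optional named topology vector; when `NULL`, circularity is
#'   inferred from exact terminal repeats (>= 20 bp).
#' @inheritParams annotated_genome
#' @return An `annotated_genome`.
#' @export
load_annotated_genome <- function(sequence_file, annotation_file,
                                  format = c("auto", "gff3", "tsv"),
                                  source_class = c("isolate_genome", "metagenome"),
                                  topology = NULL, ...) {
  format <- match.arg(format)
  source_class <- match.arg(source_class)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", annotation_file, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  seqs <- Biostrings::readDNAStringSet(sequence_file)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))

  genes <- if (format == "gff3") .read_genes_gff3(annotation_file)
           else .read_genes_tsv(annotation_file)
  if (is.null(topology)) {
    topology <- vapply(contigs, infer_topology, character(1))
  }
  annotated_genome(contigs, genes, topology = topology,
                   source_class = source_class, ...)
}

.read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "tRNA")
  if (!any(keep)) keep <- type %in% "CDS"
  gr <- gr[keep]; type <- type[keep]
  n <- length(gr)
  if (n == 0L)
    return(NULL)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, n)
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    ids[is.na(ids)] <- lt[is.na(ids)]
  }
  ids[is.na(ids)] <- paste0(as.character(GenomicRanges::seqnames(gr))[is.na(ids)],
                            "_g", which(is.na(ids)))
  labels <- if (!is.null(gr$product)) {
    vapply(as.list(gr$product), function(x)
      paste(x[!is.na(x)], collapse = ";"), character(1))
  } else rep("", n)
  transl <- if (!is.null(gr$translation)) {
    tr <- gr$translation
    if (is.list(tr) || methods::is(tr, "CharacterList"))
      vapply(as.list(tr), function(x) if (length(x)) x[[1L]] else NA_character_,
             character(1))
    else as.character(tr)
  } else rep(NA_character_, n)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  data.frame(gene_id = ids,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # 1-based -> 0-based
             end = GenomicRanges::end(gr),
             strand = strand,
             translation = transl,
             annotation = labels,
             is_trna = type == "tRNA",
             stringsAsFactors = FALSE)
}

.read_genes_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "contig", "start", "end", "strand", "labels", "translation")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(NULL)
  tab$translation[!is.na(tab$translation) & tab$translation == ""] <- NA_character_
  data.frame(gene_id = as.character(tab$gene_id),
             contig_id = as.character(tab$contig),
             start = as.integer(tab$start) - 1L,
             end = as.integer(tab$end),
             strand = as.character(tab$strand),
             translation = as.character(tab$translation),
             annotation = ifelse(is.na(tab$labels), "", as.character(tab$labels)),
             stringsAsFactors = FALSE)
}

#' Write an annotated genome to FASTA + gene TSV (+ optional GFF3)
#'
#' The tabular dialect written here is the one [load_annotated_genome()]
#' reads back; coordinates are emitted 1-based inclusive.
#'
#' @param genome An `annotated_genome`.
#' @param fasta_path,genes_path,gff3_path Output paths (`gff3_path` optional).
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, genes_path, gff3_path = NULL) {
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path)
  g <- genome$genes
  tab <- data.frame(gene_id = g$gene_id, contig = g$contig_id,
                    start = g$start + 1L, end = g$end, strand = g$strand,
                    labels = g$annotation,
                    translation = ifelse(is.na(g$translation), "", g$translation),
                    stringsAsFactors = FALSE)
  write.table(tab, genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff3_path)) {
    if (nrow(g)) {
      gr <- GenomicRanges::GRanges(
        seqnames = g$contig_id,
        ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
        strand = g$strand)
      gr$type <- ifelse(g$is_trna, "tRNA", "gene")
      gr$ID <- g$gene_id
      gr$product <- IRanges::CharacterList(gene_labels(g$annotation))
      rtracklayer::export(gr, gff3_path, format = "gff3")
    } else {
      writeLines("##gff-version 3", gff3_path)
    }
  }
  invisible(genome)
}

# ---- prediction I/O ---------------------------------------------------------

.prediction_columns <- c("prediction_id", "genome_id", "contig_id", "start",
                         "end", "gene_start", "gene_end", "pi_gene_id",
                         "window_score", "completeness", "tandem", "att_seq",
                         "att_left_start", "att_left_end", "att_right_start",
                         "att_right_end", "att_context")

#' Empty prediction table
#'
#' @return A zero-row `inovirus_predictions` data frame with the standard
#'   columns (0-based half-open coordinates internally).
#' @export
empty_predictions <- function() {
  out <- data.frame(prediction_id = character(), genome_id = character(),
                    contig_id = character(), start = integer(), end = integer(),
                    gene_start = integer(), gene_end = integer(),
                    pi_gene_id = character(), window_score = double(),
                    completeness = character(), tandem = logical(),
                    att_seq = character(), att_left_start = integer(),
                    att_left_end = integer(), att_right_start = integer(),
                    att_right_end = integer(), att_context = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("inovirus_predictions", "data.frame")
  out
}

.as_predictions <- function(df) {
  out <- empty_predictions()
  if (nrow(df) == 0L) return(out)
  for (cn in .prediction_columns)
    if (is.null(df[[cn]])) df[[cn]] <- out[[cn]][NA_integer_]
  df <- df[, .prediction_columns, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("inovirus_predictions", "data.frame")
  df
}

#' Write predictions as GFF3 + TSV
#'
#' GFF3 and TSV are 1-based inclusive; the TSV carries the full record
#' (completeness class, window score, att coordinates) and round-trips
#' losslessly through [read_predictions()].
#'
#' @param predictions An `inovirus_predictions` table (possibly empty).
#' @param gff3_path,tsv_path Output paths.
#' @return Invisibly, the predictions.
#' @export
write_predictions <- function(predictions, gff3_path, tsv_path) {
  p <- predictions
  if (nrow(p)) {
    gr <- GenomicRanges::GRanges(
      seqnames = p$contig_id,
      ranges = IRanges::IRanges(start = p$start + 1L, end = p$end))
    gr$type <- "prophage"
    gr$ID <- p$prediction_id
    gr$completeness <- p$completeness
    gr$score_rf <- p$window_score
    rtracklayer::export(gr, gff3_path, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff3_path)
  }
  tab <- as.data.frame(p)
  # 0-based half-open -> 1-based inclusive for every coordinate pair
  for (cn in c("start", "att_left_start", "att_right_start"))
    tab[[cn]] <- tab[[cn]] + 1L
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(predictions)
}

#' Read back a prediction TSV written by [write_predictions()]
#'
#' @param tsv_path Path to the TSV report.
#' @return An `inovirus_predictions` table (internal coordinates).
#' @export
read_predictions <- function(tsv_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE,
                    colClasses = c(att_seq = "character",
                                   att_context = "character"))
  if (nrow(tab) == 0L) return(empty_predictions())
  for (cn in c("start", "att_left_start", "att_right_start"))
    tab[[cn]] <- as.integer(tab[[cn]]) - 1L
  for (cn in c("end", "gene_start", "gene_end", "att_left_end", "att_right_end"))
    tab[[cn]] <- as.integer(tab[[cn]])
  tab$tandem <- as.logical(tab$tandem)
  .as_predictions(tab)
}
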