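# Synthetic annotated genomes with planted inovirus proviruses, confounder
# cassettes, att repeats, species structure and CRISPR spacers — plus full
# ground truth — so that every pipeline stage is testable without downloads.
# The generator is seed-deterministic: one RNG stream, one seed.

.NT <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.NT, n, replace = TRUE), collapse = "")

# amino-acid sampling with a composition bias per role
.polar_aa <- c("D", "E", "K", "N", "Q", "S", "T", "R", "G", "P", "H", "Y")
.polar_aa_nobasic <- setdiff(.polar_aa, c("K", "R"))
.hydro_aa <- c("L", "I", "V", "F", "A", "M")

.random_protein <- function(n, pool = .AA20) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# structural candidate: polar flanks around a single 21-residue hydrophobic
# core; no basic residue upstream of the core so the signal-peptide rule can
# never truncate it
.make_structural_protein <- function(aa_len) {
  stopifnot(aa_len >= 27L)
  core_len <- 21L
  pre <- sample.int(aa_len - core_len - 2L, 1L)
  post <- aa_len - core_len - pre
  p <- paste0(.random_protein(pre, .polar_aa_nobasic),
              .random_protein(core_len, .hydro_aa),
              .random_protein(post, .polar_aa))
  stopifnot(is_candidate_structural(p))
  p
}

# plant a motif into a protein with n_mut substitutions
.embed_motif <- function(motif, total_len, n_mut = 0L, pool = .polar_aa,
                         tail_tmd = c("none", "C", "N")) {
  tail_tmd <- match.arg(tail_tmd)
  mv <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (n_mut > 0L) {
    at <- sample(length(mv), n_mut)
    for (i in at) mv[i] <- sample(setdiff(.AA20, mv[i]), 1L)
  }
  motif <- paste(mv, collapse = "")
  tmd <- paste0(.random_protein(21L, .hydro_aa), .random_protein(3L, .polar_aa))
  rest <- total_len - nchar(motif) - if (tail_tmd == "none") 0L else nchar(tmd)
  stopifnot(rest >= 10L)
  pre <- sample.int(rest - 5L, 1L)
  body <- switch(tail_tmd,
    none = paste0(.random_protein(pre, pool), motif,
                  .random_protein(rest - pre, pool)),
    C = paste0(.random_protein(pre, pool), motif,
               .random_protein(rest - pre, pool), tmd),
    N = paste0(tmd, .random_protein(pre, pool), motif,
               .random_protein(rest - pre, pool)))
  body
}

.host_vocab <- c(
  "DNA polymerase III subunit alpha", "ABC transporter ATP-binding protein",
  "50S ribosomal protein L2", "elongation factor Tu",
  "two-component sensor histidine kinase", "glycosyltransferase family 2",
  "aminotransferase class I", "NADH-quinone oxidoreductase subunit",
  "peptidase M23 family", "TonB-dependent receptor",
  "MFS transporter", "GTP-binding protein", "cold-shock protein",
  "acyl-CoA dehydrogenase", "transcriptional regulator, LysR family")

.plasmid_vocab <- c(
  "Mobilization protein MobA", "Plasmid partitioning protein ParA",
  "Conjugal transfer protein TraG", "Plasmid stability protein StbB",
  "Relaxase MobC", "Entry exclusion protein", "Antirestriction protein ArdA")

.caudo_vocab <- c(
  "Major capsid protein", "Portal protein", "Tail fiber protein",
  "Baseplate assembly protein", "Head-tail adaptor",
  "Tail tape measure protein", "Holin", "Endolysin")

#' Simulation configuration for the synthetic benchmark
#'
#' Defaults define the benchmark conditions: 50 host genomes, 25 planted
#' inovirus proviruses and 25 hard-negative cassettes (plasmid-like and
#' Caudovirales-like), host genes drawn from a lognormal with median 900 nt,
#' inovirus cassettes of 6-12 genes with median length ~300 nt carrying at
#' least two 30-90 aa single-TMD structural candidates and one pI-like gene
#' with the seed motif, 14-bp att direct repeats, and a CRISPR spacer library
#' sampled from the planted proviruses with 0-2 mismatches.
#'
#' @param seed Random seed (drives everything).
#' @param n_genomes Number of host genomes.
#' @param n_inovirus Number of genomes with a planted inovirus.
#' @param n_plasmid,n_caudo Numbers of hard-negative cassettes.
#' @param host_genes Host genes per genome.
#' @param host_gene_meanlog,host_gene_sdlog Lognormal host gene length (nt).
#' @param cassette_genes Range of inovirus cassette gene counts.
#' @param n_structural Range of structural-candidate genes per cassette.
#' @param rcr_prob Probability the cassette carries a replication-initiation
#'   (RCR endonuclease) labelled gene.
#' @param pi_mutations Substitutions applied to the planted pI motif (0-3).
#' @param atypical_pi_fraction Fraction of pI genes with an N-terminal
#'   instead of C-terminal TMD.
#' @param att_len att direct-repeat length (bp).
#' @param trna_fraction Fraction of integrated proviruses whose left att copy
#'   overlaps a planted tRNA gene (canonical integration).
#' @param frac_circular Fraction of inovirus plantings emitted as circular
#'   contigs (complete genomes) instead of integrated proviruses.
#' @param decoy_fraction Fraction of confounder cassettes carrying a diverged
#'   ATPase decoy that still passes the marker filter (hard negatives for the
#'   classifier, not just for the marker gate).
#' @param decoy_mutations Substitutions applied to the decoy motif.
#' @param n_species Number of distinct species among the plantings (`NULL` =
#'   all independent); replicates of a species parent are mutated at
#'   `within_species_divergence`.
#' @param within_species_divergence Per-site substitution fraction applied to
#'   species replicates (exact count).
#' @param n_spacers Number of CRISPR spacers sampled from plantings.
#' @param spacer_mismatch_probs Probabilities of 0/1/2 planted mismatches.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 42L, n_genomes = 50L, n_inovirus = 25L,
                              n_plasmid = 13L, n_caudo = 12L,
                              host_genes = 40L,
                              host_gene_meanlog = log(900),
                              host_gene_sdlog = 0.35,
                              cassette_genes = c(6L, 12L),
                              n_structural = c(2L, 3L),
                              rcr_prob = 0.7,
                              pi_mutations = c(0L, 3L),
                              atypical_pi_fraction = 0.3,
                              att_len = 14L,
                              trna_fraction = 0.5,
                              frac_circular = 0.2,
                              decoy_fraction = 0.7,
                              decoy_mutations = 10L,
                              n_species = NULL,
                              within_species_divergence = 0.02,
                              n_spacers = 30L,
                              spacer_mismatch_probs = c(0.5, 0.3, 0.2)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_inovirus + cfg$n_plasmid + cfg$n_caudo <= cfg$n_genomes,
            cfg$att_len >= 10L,
            all(vapply(list(rcr_prob, atypical_pi_fraction, trna_fraction,
                            frac_circular, decoy_fraction,
                            within_species_divergence),
                       function(x) x >= 0 && x <= 1, logical(1))))
  class(cfg) <- "sim_config"
  cfg
}

#' Apply an exact number of substitutions to a nucleotide sequence
#'
#' `round(divergence * nchar(seq))` positions are sampled without replacement
#' and each is changed to a different base, so the realized divergence equals
#' the nominal one exactly. Uses the current RNG stream.
#'
#' @param seq Nucleotide string.
#' @param divergence Substitution fraction in `[0, 1]`.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, divergence) {
  n <- nchar(seq)
  m <- round(divergence * n)
  if (m == 0L) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  at <- sample(n, m)
  for (i in at) v[i] <- sample(setdiff(.NT, v[i]), 1L)
  paste(v, collapse = "")
}

# --- cassette builders ------------------------------------------------------
# a cassette is list(seq, genes = data.frame(rel start/end, strand,
# translation, annotation), n_pi)

.build_gene_run <- function(aa_lens, translations, annotations, strands,
                            gap_range = c(5L, 60L)) {
  n <- length(aa_lens)
  nt_lens <- 3L * (aa_lens + 1L)
  gaps <- sample(gap_range[1L]:gap_range[2L], n, replace = TRUE)
  starts <- cumsum(gaps + c(0L, nt_lens[-n]))
  ends <- starts + nt_lens
  total <- ends[n] + sample(gap_range[1L]:gap_range[2L], 1L)
  data.frame(start = starts, end = ends, strand = strands,
             translation = translations, annotation = annotations,
             total = total, stringsAsFactors = FALSE)
}

.make_inovirus_cassette <- function(cfg) {
  n <- sample(cfg$cassette_genes[1L]:cfg$cassette_genes[2L], 1L)
  n_struct <- min(sample(cfg$n_structural[1L]:cfg$n_structural[2L], 1L), n - 2L)
  roles <- c("pI", rep("structural", n_struct),
             rep("other", n - 1L - n_struct))
  if (runif(1) < cfg$rcr_prob && sum(roles == "other") >= 1L)
    roles[which(roles == "other")[1L]] <- "rcr"
  roles <- sample(roles)
  aa <- integer(n); tr <- character(n); ann <- character(n)
  for (i in seq_len(n)) {
    if (roles[i] == "pI") {
      aa[i] <- sample(150:220, 1L)
      topo <- if (runif(1) < cfg$atypical_pi_fraction) "N" else "C"
      tr[i] <- .embed_motif(.pi_consensus, aa[i],
                            n_mut = sample(cfg$pi_mutations[1L]:cfg$pi_mutations[2L], 1L),
                            pool = .polar_aa, tail_tmd = topo)
      ann[i] <- ""
    } else if (roles[i] == "structural") {
      aa[i] <- sample(30:80, 1L)
      tr[i] <- .make_structural_protein(aa[i])
      ann[i] <- ""
    } else if (roles[i] == "rcr") {
      aa[i] <- sample(90:140, 1L)
      tr[i] <- .random_protein(aa[i], .polar_aa)
      ann[i] <- "Replication initiation protein (RCR endonuclease)"
    } else {
      aa[i] <- sample(60:130, 1L)
      tr[i] <- .random_protein(aa[i], .polar_aa)
      ann[i] <- ""
    }
  }
  strand_main <- sample(c("+", "-"), 1L)
  strands <- ifelse(runif(n) < 0.9, strand_main,
                    setdiff(c("+", "-"), strand_main))
  genes <- .build_gene_run(aa, tr, ann, strands)
  list(seq = .random_dna(genes$total[1L]), genes = genes, n_pi = 1L,
       pi_topology = NULL)
}

.make_confounder_cassette <- function(cfg, kind = c("plasmid", "caudo")) {
  kind <- match.arg(kind)
  n <- if (kind == "plasmid") sample(6:10, 1L) else sample(8:12, 1L)
  vocab <- if (kind == "plasmid") .plasmid_vocab else .caudo_vocab
  aa <- if (kind == "plasmid") sample(80:150, n, replace = TRUE)
        else sample(100:250, n, replace = TRUE)
  tr <- vapply(aa, .random_protein, character(1), pool = .polar_aa)
  ann <- ifelse(runif(n) < 0.75, sample(vocab, n, replace = TRUE), "")
  if (kind == "caudo") {
    aa[1L] <- 280L
    tr[1L] <- .embed_motif(.terminase_consensus, aa[1L], n_mut = 2L,
                           pool = .polar_aa)
    ann[1L] <- "Terminase large subunit"
  }
  if (runif(1) < cfg$decoy_fraction) {
    i <- n  # last gene becomes the diverged ATPase decoy
    aa[i] <- 250L
    tr[i] <- .embed_motif(.pi_consensus, aa[i], n_mut = cfg$decoy_mutations,
                          pool = .polar_aa)
    ann[i] <- "AAA family ATPase"
  }
  strands <- ifelse(runif(n) < 0.9, "+", "-")
  genes <- .build_gene_run(aa, tr, ann, strands)
  list(seq = .random_dna(genes$total[1L]), genes = genes, n_pi = 0L)
}

.make_host_backbone <- function(cfg) {
  n <- cfg$host_genes
  nt <- 3L * (pmax(80L, round(rlnorm(n, cfg$host_gene_meanlog,
                                     cfg$host_gene_sdlog) / 3)) )
  aa <- nt / 3L - 1L
  tr <- vapply(aa, .random_protein, character(1))
  ann <- ifelse(runif(n) < 0.75, sample(.host_vocab, n, replace = TRUE), "")
  # operon-like strand persistence
  strands <- character(n); strands[1L] <- sample(c("+", "-"), 1L)
  for (i in seq_len(n)[-1L])
    strands[i] <- if (runif(1) < 0.8) strands[i - 1L]
                  else setdiff(c("+", "-"), strands[i - 1L])
  genes <- .build_gene_run(aa, tr, ann, strands, gap_range = c(20L, 150L))
  list(seq = .random_dna(genes$total[1L]), genes = genes)
}

# best direct-repeat pair (length desc, distance asc) between two flank
# strings; NULL if none >= k. Used by the generator's recoverability assert.
.top_repeat_pair <- function(left, right, k) {
  nl <- nchar(left); nr <- nchar(right)
  if (nl < k || nr < k) return(NULL)
  lk <- substring(left, 1:(nl - k + 1L), k:nl)
  rk <- substring(right, 1:(nr - k + 1L), k:nr)
  l_index <- split(seq_len(nl - k + 1L), lk)
  lv <- strsplit(left, "", fixed = TRUE)[[1L]]
  rv <- strsplit(right, "", fixed = TRUE)[[1L]]
  best <- NULL
  for (j in seq_len(nr - k + 1L)) {
    starts <- l_index[[rk[j]]]
    if (is.null(starts)) next
    for (i in starts) {
      a <- i; b <- j
      while (a > 1L && b > 1L && lv[a - 1L] == rv[b - 1L]) { a <- a - 1L; b <- b - 1L }
      ea <- i + k - 1L; eb <- j + k - 1L
      while (ea < nl && eb < nr && lv[ea + 1L] == rv[eb + 1L]) { ea <- ea + 1L; eb <- eb + 1L }
      len <- ea - a + 1L
      dist <- (nl - ea) + (b - 1L)
      if (is.null(best) || len > best$len ||
          (len == best$len && dist < best$dist))
        best <- list(a = a, b = b, len = len, dist = dist)
    }
  }
  best
}

#' Generate a synthetic benchmark fixture
#'
#' Builds `n_genomes` annotated host genomes; plants an inovirus cassette
#' (integrated between att direct repeats, or as a circular contig) in
#' `n_inovirus` of them and a hard-negative cassette (plasmid-like or
#' Caudovirales-like, optionally carrying a diverged ATPase decoy) in the
#' rest; samples a CRISPR spacer library from the plantings; and returns full
#' ground truth. Byte-reproducible given the config seed. Planted regions
#' satisfy the detector's feature assumptions by construction (short,
#' mostly unannotated genes; >= 2 structural candidates; pI motif present),
#' planted att repeats are asserted to be the top-ranked recoverable repeat
#' pair in their flanks, and planted structural proteins are asserted to pass
#' [is_candidate_structural()].
#'
#' @param config A [simulation_config()].
#' @return A list of class `inovirus_fixture`: `genomes` (named list of
#'   `annotated_genome`), `truth` (data frame; 0-based half-open spans),
#'   `spacers` (named character), `spacer_info`, `config`.
#' @export
generate_fixture <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  roles <- sample(c(rep("inovirus", cfg$n_inovirus),
                    rep("plasmid", cfg$n_plasmid),
                    rep("caudo", cfg$n_caudo),
                    rep("clean", cfg$n_genomes - cfg$n_inovirus -
                          cfg$n_plasmid - cfg$n_caudo)))
  # species structure for the inovirus plantings
  ino_idx <- which(roles == "inovirus")
  n_sp <- if (is.null(cfg$n_species)) length(ino_idx) else
    min(cfg$n_species, length(ino_idx))
  species_of <- if (length(ino_idx))
    sort(rep_len(seq_len(n_sp), length(ino_idx))) else integer(0)
  parents <- replicate(n_sp, .make_inovirus_cassette(cfg), simplify = FALSE)
  circular_flags <- if (length(ino_idx))
    seq_along(ino_idx) <= round(cfg$frac_circular * length(ino_idx)) else logical(0)

  genomes <- list()
  truth_rows <- list()
  ino_counter <- 0L
  for (gi in seq_len(cfg$n_genomes)) {
    gid <- sprintf("genome_%02d", gi)
    cid <- sprintf("%s_c1", gid)
    role <- roles[gi]
    if (role == "inovirus") {
      ino_counter <- ino_counter + 1L
      sp <- species_of[ino_counter]
      cass <- parents[[sp]]
      if (sum(species_of == sp) > 1L && ino_counter > match(sp, species_of))
        cass$seq <- mutate_sequence(cass$seq, cfg$within_species_divergence)
      if (circular_flags[ino_counter]) {
        # complete genome: circular contig holding only the cassette
        seq <- paste0(cass$seq, substr(cass$seq, 1L, 20L))
        genes <- cass$genes
        genes$gene_id <- sprintf("%s_g%03d", cid, seq_len(nrow(genes)))
        genes$contig_id <- cid
        genomes[[gid]] <- annotated_genome(
          setNames(seq, cid), genes, topology = setNames("circular", cid))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          truth_id = sprintf("truth_%02d", length(truth_rows) + 1L),
          genome_id = gid, contig_id = cid, start = 0L, end = nchar(seq),
          type = "inovirus", circular = TRUE,
          att_left_start = NA_integer_, att_left_end = NA_integer_,
          att_right_start = NA_integer_, att_right_end = NA_integer_,
          species_id = sprintf("truth_sp_%02d", sp), n_pi = 1L,
          stringsAsFactors = FALSE)
        next
      }
      host <- .make_host_backbone(cfg)
      ok <- FALSE
      for (try in 1:30) {
        att <- .random_dna(cfg$att_len)
        cut_gene <- sample(5:(nrow(host$genes) - 5L), 1L)
        cut <- host$genes$end[cut_gene] +
          sample(10:(host$genes$start[cut_gene + 1L] - host$genes$end[cut_gene] - 10L), 1L)
        ins_len <- 2L * cfg$att_len + nchar(cass$seq)
        seq <- paste0(substr(host$seq, 1L, cut), att, cass$seq, att,
                      substr(host$seq, cut + 1L, nchar(host$seq)))
        span <- c(cut, cut + ins_len)
        # recoverability check relative to the *cassette* span: the att
        # copies sit in the flanks of the gene window the detector scores
        inner1 <- cut + cfg$att_len
        inner2 <- inner1 + nchar(cass$seq)
        flank <- 2500L
        l0 <- max(0L, inner1 - flank)
        r1 <- min(nchar(seq), inner2 + flank)
        top <- .top_repeat_pair(substr(seq, l0 + 1L, inner1),
                                substr(seq, inner2 + 1L, r1),
                                cfg$att_len)
        # the planted att must be the top-ranked pair (possibly extended by
        # coincidental flanking matches)
        if (!is.null(top) && top$len >= cfg$att_len &&
            l0 + top$a - 1L + top$len == inner1 &&
            top$b == 1L) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible geometry: could not plant a recoverable att")
      hg <- host$genes
      after <- hg$start >= cut
      hg$start[after] <- hg$start[after] + ins_len
      hg$end[after] <- hg$end[after] + ins_len
      cg <- cass$genes
      cg$start <- cg$start + cut + cfg$att_len
      cg$end <- cg$end + cut + cfg$att_len
      cg$total <- NULL; hg$total <- NULL
      genes <- rbind(hg, cg)
      # att copies: left at [cut, cut+att_len), right at [span2-att_len, span2)
      att_left <- c(cut, cut + cfg$att_len)
      att_right <- c(span[2L] - cfg$att_len, span[2L])
      if (runif(1) < cfg$trna_fraction) {
        genes <- rbind(genes, data.frame(
          start = cut - 40L, end = cut + 20L, strand = "+",
          translation = NA_character_, annotation = "tRNA-Met",
          stringsAsFactors = FALSE))
      }
      genes <- genes[order(genes$start), , drop = FALSE]
      genes$gene_id <- sprintf("%s_g%03d", cid, seq_len(nrow(genes)))
      genes$contig_id <- cid
      genomes[[gid]] <- annotated_genome(setNames(seq, cid), genes)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        truth_id = sprintf("truth_%02d", length(truth_rows) + 1L),
        genome_id = gid, contig_id = cid,
        start = span[1L], end = span[2L],
        type = "inovirus", circular = FALSE,
        att_left_start = att_left[1L], att_left_end = att_left[2L],
        att_right_start = att_right[1L], att_right_end = att_right[2L],
        species_id = sprintf("truth_sp_%02d", sp), n_pi = 1L,
        stringsAsFactors = FALSE)
    } else {
      host <- .make_host_backbone(cfg)
      seq <- host$seq
      genes <- host$genes
      if (role != "clean") {
        cass <- .make_confounder_cassette(
          cfg, if (role == "plasmid") "plasmid" else "caudo")
        cut_gene <- sample(5:(nrow(genes) - 5L), 1L)
        cut <- genes$end[cut_gene] + 10L
        ins_len <- nchar(cass$seq)
        seq <- paste0(substr(seq, 1L, cut), cass$seq,
                      substr(seq, cut + 1L, nchar(seq)))
        after <- genes$start >= cut
        genes$start[after] <- genes$start[after] + ins_len
        genes$end[after] <- genes$end[after] + ins_len
        cg <- cass$genes
        cg$start <- cg$start + cut
        cg$end <- cg$end + cut
        cg$total <- NULL
        genes$total <- NULL
        genes <- rbind(genes, cg)
        genes <- genes[order(genes$start), , drop = FALSE]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          truth_id = sprintf("truth_%02d", length(truth_rows) + 1L),
          genome_id = gid, contig_id = cid, start = cut, end = cut + ins_len,
          type = paste0(if (role == "plasmid") "plasmid" else "caudovirales",
                        "_confounder"),
          circular = FALSE,
          att_left_start = NA_integer_, att_left_end = NA_integer_,
          att_right_start = NA_integer_, att_right_end = NA_integer_,
          species_id = NA_character_, n_pi = 0L, stringsAsFactors = FALSE)
      }
      genes$total <- NULL
      genes$gene_id <- sprintf("%s_g%03d", cid, seq_len(nrow(genes)))
      genes$contig_id <- cid
      genomes[[gid]] <- annotated_genome(setNames(seq, cid), genes)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  # CRISPR spacer library sampled from the planted inovirus regions
  spacers <- character(0); sp_info <- list()
  ino_truth <- truth[truth$type == "inovirus", , drop = FALSE]
  if (cfg$n_spacers > 0L && nrow(ino_truth) > 0L) {
    for (si in seq_len(cfg$n_spacers)) {
      t <- ino_truth[sample(nrow(ino_truth), 1L), ]
      seq <- genomes[[t$genome_id]]$contigs[[t$contig_id]]
      len <- sample(28:35, 1L)
      at <- sample((t$start + 1L):(t$end - len), 1L)
      sp <- substr(seq, at, at + len - 1L)
      m <- sample(0:2, 1L, prob = cfg$spacer_mismatch_probs)
      if (m > 0L) sp <- mutate_sequence(sp, m / nchar(sp))
      if (runif(1) < 0.5) sp <- .revcomp(sp)
      sid <- sprintf("spacer_%03d", si)
      spacers[[sid]] <- sp
      sp_info[[si]] <- data.frame(
        spacer_id = sid, genome_id = t$genome_id, truth_id = t$truth_id,
        n_mut = m, stringsAsFactors = FALSE)
    }
  }
  structure(list(genomes = genomes, truth = truth, spacers = spacers,
                 spacer_info = if (length(sp_info)) do.call(rbind, sp_info)
                               else NULL,
                 config = cfg),
            class = "inovirus_fixture")
}

#' @export
print.inovirus_fixture <- function(x, ...) {
  cat("<inovirus_fixture> ", length(x$genomes), " genome(s), ",
      sum(x$truth$type == "inovirus"), " planted inovirus, ",
      sum(x$truth$type != "inovirus"), " confounder(s), ",
      length(x$spacers), " spacer(s)\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk in the formats the package reads
#'
#' Per genome: FASTA, gene TSV and GFF3; plus truth as BED (0-based) and TSV
#' (1-based), and the spacer library as FASTA.
#'
#' @param fixture An `inovirus_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gid in names(fixture$genomes)) {
    write_genome(fixture$genomes[[gid]],
                 file.path(dir, paste0(gid, ".fna")),
                 file.path(dir, paste0(gid, "_genes.tsv")),
                 file.path(dir, paste0(gid, ".gff3")))
  }
  t <- fixture$truth
  bed <- data.frame(chrom = t$contig_id, start = t$start, end = t$end,
                    name = t$truth_id, score = 0L, strand = "+")
  write.table(bed, file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  t1 <- t; t1$start <- t1$start + 1L
  write.table(t1, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(fixture$spacers))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(fixture$spacers),
      file.path(dir, "spacers.fasta"))
  invisible(dir)
}

#' Build a labelled training set from a fixture's ground truth
#'
#' Positive windows are the gene spans of planted inovirus regions; negative
#' windows are the confounder cassette gene spans, `n_background` random host
#' windows per genome that avoid all planted regions, and — when
#' `overhangs > 0` — every planted window extended by 1..`overhangs` host
#' genes on either or both sides. Overhang negatives sharpen localization but
#' also drag true-window scores towards the decision boundary, so they are
#' off by default; window-extent noise is instead absorbed by the nested
#' boundary refinement in [detect_inoviruses()].
#'
#' @param fixture An `inovirus_fixture`.
#' @param n_background Random background windows per genome.
#' @param overhangs Maximum overhang (genes per side) for hard negatives
#'   (default 0 = none).
#' @return `list(x = feature matrix, y = factor background/inovirus)`.
#' @export
training_features <- function(fixture, n_background = 2L, overhangs = 0L) {
  xs <- list(); ys <- character(0)
  for (gid in names(fixture$genomes)) {
    gen <- fixture$genomes[[gid]]
    tr <- fixture$truth[fixture$truth$genome_id == gid, , drop = FALSE]
    for (cid in names(gen$contigs)) {
      g <- gen$genes[gen$genes$contig_id == cid, , drop = FALSE]
      if (nrow(g) == 0L) next
      tc <- tr[tr$contig_id == cid, , drop = FALSE]
      in_truth <- rep(FALSE, nrow(g))
      if (nrow(tc)) for (r in seq_len(nrow(tc))) {
        inside <- which(g$start >= tc$start[r] & g$end <= tc$end[r])
        if (length(inside)) {
          w <- range(inside)
          xs[[length(xs) + 1L]] <- extract_features(gen, cid, w)
          ys <- c(ys, if (tc$type[r] == "inovirus") "inovirus" else "background")
          in_truth[inside] <- TRUE
          if (overhangs > 0L) for (ext in seq_len(overhangs)) {
            for (ov in list(c(-ext, 0L), c(0L, ext), c(-ext, ext))) {
              w2 <- c(max(1L, w[1L] + ov[1L]), min(nrow(g), w[2L] + ov[2L]))
              if (identical(w2, w)) next
              xs[[length(xs) + 1L]] <- extract_features(gen, cid, w2)
              ys <- c(ys, "background")
            }
          }
        }
      }
      free <- which(!in_truth)
      for (b in seq_len(n_background)) {
        if (length(free) < 6L) break
        w <- sample(6:12, 1L)
        starts <- free[free + w - 1L <= max(free)]
        starts <- starts[vapply(starts, function(s)
          all((s:(s + w - 1L)) %in% free), logical(1))]
        if (length(starts) == 0L) break
        s <- sample(starts, 1L)
        xs[[length(xs) + 1L]] <- extract_features(gen, cid, c(s, s + w - 1L))
        ys <- c(ys, "background")
      }
    }
  }
  list(x = do.call(rbind, xs),
       y = factor(ys, levels = c("background", "inovirus")))
}

#' Score predictions against planted truth
#'
#' A prediction is a true positive when it has reciprocal overlap of at least
#' `overlap` with an inovirus truth span on the same contig (greedy 1-1
#' matching by decreasing overlap). Recall is matched truths / planted
#' inoviruses; precision is matched predictions / all predictions (an empty
#' prediction set reports precision 1 with `zero_call = TRUE`). Boundary
#' error statistics are att-coordinate offsets over matched pairs where both
#' sides annotate an att site.
#'
#' @param predictions An `inovirus_predictions` table with `genome_id` set.
#' @param truth Fixture truth table.
#' @param overlap Reciprocal-overlap threshold (default 0.5).
#' @return `list(recall, precision, n_pred, n_truth, tp, zero_call, matches,
#'   boundary_error)`.
#' @export
score_against_truth <- function(predictions, truth, overlap = 0.5) {
  ino <- truth[truth$type == "inovirus", , drop = FALSE]
  n_truth <- nrow(ino); n_pred <- nrow(predictions)
  if (n_pred == 0L)
    return(list(recall = 0, precision = 1, n_pred = 0L, n_truth = n_truth,
                tp = 0L, zero_call = TRUE, matches = NULL,
                boundary_error = NULL))
  cand <- list()
  for (p in seq_len(n_pred)) for (t in seq_len(n_truth)) {
    if (predictions$genome_id[p] != ino$genome_id[t] ||
        predictions$contig_id[p] != ino$contig_id[t]) next
    inter <- min(predictions$end[p], ino$end[t]) -
      max(predictions$start[p], ino$start[t])
    if (inter <= 0) next
    ro <- min(inter / (predictions$end[p] - predictions$start[p]),
              inter / (ino$end[t] - ino$start[t]))
    if (ro >= overlap)
      cand[[length(cand) + 1L]] <- c(p = p, t = t, ro = ro)
  }
  used_p <- logical(n_pred); used_t <- logical(n_truth)
  match_rows <- list()
  if (length(cand)) {
    m <- do.call(rbind, cand)
    m <- m[order(-m[, "ro"]), , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      p <- m[r, "p"]; t <- m[r, "t"]
      if (used_p[p] || used_t[t]) next
      used_p[p] <- TRUE; used_t[t] <- TRUE
      match_rows[[length(match_rows) + 1L]] <- data.frame(
        prediction_id = predictions$prediction_id[p],
        truth_id = ino$truth_id[t], overlap = m[r, "ro"],
        left_err = abs(predictions$att_left_start[p] - ino$att_left_start[t]),
        right_err = abs(predictions$att_right_end[p] - ino$att_right_end[t]),
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else NULL
  tp <- sum(used_t)
  be <- NULL
  if (!is.null(matches)) {
    ok <- !is.na(matches$left_err) & !is.na(matches$right_err)
    if (any(ok))
      be <- list(mean = mean(c(matches$left_err[ok], matches$right_err[ok])),
                 median = median(c(matches$left_err[ok], matches$right_err[ok])),
                 n = sum(ok))
  }
  list(recall = tp / n_truth, precision = sum(used_p) / n_pred,
       n_pred = n_pred, n_truth = n_truth, tp = tp, zero_call = FALSE,
       matches = matches, boundary_error = be)
}

#' Run detection over every genome of a fixture
#'
#' @param fixture An `inovirus_fixture`.
#' @param classifier An `inovirus_classifier`.
#' @param models Marker models (default: the synthetic pI seed model).
#' @param flank_bp att search distance (default 2500, matched to the compact
#'   synthetic genomes).
#' @param ... Passed to [detect_inoviruses()].
#' @return Combined `inovirus_predictions` across genomes.
#' @export
detect_fixture <- function(fixture, classifier,
                           models = list(inovirus_seed_model()),
                           flank_bp = 2500L, ...) {
  preds <- lapply(names(fixture$genomes), function(gid)
    detect_inoviruses(fixture$genomes[[gid]], classifier, models,
                      genome_id = gid, flank_bp = flank_bp, ...))
  out <- do.call(rbind, preds)
  .as_predictions(out)
}
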