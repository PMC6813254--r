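# Gene-content taxonomy: a bipartite genome-PC network, two-level community
# detection (proposed families / subfamilies), and a summary-network export.
# The contract is planted-block recovery, not algorithm identity; the default
# backend is igraph's Infomap (map equation).

#' Build the bipartite genome-PC network
#'
#' Genomes and PCs are nodes; an edge connects a genome to a PC when the
#' genome encodes at least one member protein of the PC (edge multiplicity
#' collapsed to 1). Tandem genomes (>= 2 pI genes) are excluded, as are PCs
#' with fewer than 2 protein members.
#'
#' @param memberships `data.frame(genome_id, pc_id)`: one row per
#'   (genome, PC) incidence (duplicates allowed, collapsed).
#' @param pc_sizes Named integer vector: pc_id -> number of member proteins.
#' @param pi_counts Named integer vector: genome_id -> number of pI genes
#'   (default 1 for genomes not listed).
#' @return `list(edges, genomes, pcs)` of class `bipartite_network`.
#' @export
build_bipartite <- function(memberships, pc_sizes, pi_counts = NULL) {
  stopifnot(all(c("genome_id", "pc_id") %in% names(memberships)))
  stopifnot(all(memberships$pc_id %in% names(pc_sizes)))
  m <- unique(memberships[, c("genome_id", "pc_id")])
  if (!is.null(pi_counts)) {
    tandem <- names(pi_counts)[pi_counts >= 2L]
    m <- m[!(m$genome_id %in% tandem), , drop = FALSE]
  }
  m <- m[pc_sizes[m$pc_id] >= 2L, , drop = FALSE]
  rownames(m) <- NULL
  structure(list(edges = m,
                 genomes = sort(unique(m$genome_id)),
                 pcs = sort(unique(m$pc_id))),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  ng <- length(x$genomes); np <- length(x$pcs); ne <- nrow(x$edges)
  dens <- if (ng > 0 && np > 0) ne / (ng * np) else NA_real_
  cat("<bipartite_network> ", ng, " genome(s) x ", np, " PC(s), ",
      ne, " edge(s), density ", signif(100 * dens, 3), "%\n", sep = "")
  invisible(x)
}

.bipartite_graph <- function(network) {
  # prefix node names so genome and PC ids can never collide
  e <- network$edges
  igraph::graph_from_data_frame(
    data.frame(from = paste0("g::", e$genome_id),
               to = paste0("pc::", e$pc_id)),
    directed = FALSE,
    vertices = c(paste0("g::", network$genomes),
                 paste0("pc::", network$pcs)))
}

#' Two-level gene-content clustering of the bipartite network
#'
#' Level 1 (proposed families): Infomap communities of the full bipartite
#' graph. Level 2 (proposed subfamilies): Infomap within each level-1
#' community's subgraph. Deterministic given `seed`; genomes with no PC path
#' between them can never share a group (communities never span disconnected
#' components).
#'
#' @param network A `bipartite_network` (non-empty).
#' @param seed Random seed.
#' @return `data.frame(genome_id, group, subgroup)` covering every networked
#'   genome; subgroup ids are nested in group ids (`"G1.S2"`).
#' @export
cluster_two_level <- function(network, seed = 42L) {
  if (length(network$genomes) == 0L || nrow(network$edges) == 0L)
    stop("empty bipartite network")
  g <- .bipartite_graph(network)
  set.seed(seed)
  mem1 <- igraph::membership(igraph::cluster_infomap(g))
  groups <- split(names(mem1), as.integer(mem1))
  # stable group order: size descending, then smallest member
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  groups <- groups[ord]
  rows <- list()
  for (gi in seq_along(groups)) {
    nodes <- groups[[gi]]
    sub <- igraph::induced_subgraph(g, nodes)
    set.seed(seed + gi)
    mem2 <- if (igraph::ecount(sub) > 0L)
      igraph::membership(igraph::cluster_infomap(sub))
    else setNames(rep(1L, length(nodes)), nodes)
    sgroups <- split(names(mem2), as.integer(mem2))
    sord <- order(-lengths(sgroups), vapply(sgroups, min, character(1)))
    sgroups <- sgroups[sord]
    for (si in seq_along(sgroups)) {
      gn <- sgroups[[si]][startsWith(sgroups[[si]], "g::")]
      if (length(gn) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = substring(gn, 4L),
        group = paste0("G", gi),
        subgroup = paste0("G", gi, ".S", si),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the network at subgroup resolution
#'
#' Collapses genomes into their subgroups: each subgroup becomes a node with
#' size attribute log10(member count), and an edge is drawn to a PC when more
#' than 50% of the subgroup's genomes encode it — or more than 25% for the
#' largest subgroup, which is diverse enough that few PCs clear the majority
#' bar.
#'
#' @param network A `bipartite_network`.
#' @param assignments Output of [cluster_two_level()] covering the network's
#'   genomes.
#' @param largest_subgroup Subgroup id getting the 25% rule; default: the
#'   subgroup with the most genomes (ties to the first).
#' @return `list(nodes = data.frame(subgroup, n_genomes, size),
#'   edges = data.frame(subgroup, pc_id, prevalence))`.
#' @export
summarize_network <- function(network, assignments, largest_subgroup = NULL) {
  stopifnot(all(network$genomes %in% assignments$genome_id))
  counts <- table(assignments$subgroup)
  if (is.null(largest_subgroup))
    largest_subgroup <- names(counts)[which.max(counts)]
  nodes <- data.frame(subgroup = names(counts),
                      n_genomes = as.integer(counts),
                      size = log10(as.integer(counts)),
                      stringsAsFactors = FALSE)
  e <- network$edges
  sg <- setNames(assignments$subgroup, assignments$genome_id)
  e$subgroup <- unname(sg[e$genome_id])
  rows <- list()
  for (s in names(counts)) {
    n <- counts[[s]]
    es <- e[e$subgroup == s, , drop = FALSE]
    if (nrow(es) == 0L) next
    prev <- table(es$pc_id) / n
    cut <- if (s == largest_subgroup) 0.25 else 0.5
    keep <- prev > cut
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = s, pc_id = names(prev)[keep],
        prevalence = as.numeric(prev[keep]), stringsAsFactors = FALSE)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subgroup = character(), pc_id = character(),
               prevalence = double(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Export a summary network as edge-list TSV (and optionally GraphML)
#'
#' @param summary Output of [summarize_network()].
#' @param tsv_path Edge-list TSV path.
#' @param graphml_path Optional GraphML path (for Cytoscape-class viewers).
#' @return Invisibly, `summary`.
#' @export
export_summary_network <- function(summary, tsv_path, graphml_path = NULL) {
  write.table(summary$edges, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      summary$edges[, c("subgroup", "pc_id")], directed = FALSE)
    sz <- setNames(summary$nodes$size, summary$nodes$subgroup)
    igraph::V(g)$size <- unname(sz[igraph::V(g)$name])
    igraph::V(g)$size[is.na(igraph::V(g)$size)] <- 0
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(summary)
}
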