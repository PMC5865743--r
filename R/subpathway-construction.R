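#' Extract distance-based k-clique subpathways from a pathway graph
#'
#' A subpathway region is a maximal set of genes whose pairwise shortest-path
#' distance in the full pathway graph is at most `k` (a distance-based
#' "k-clique").  These sets are exactly the maximal cliques of the k-th power
#' of the pathway graph, enumerated here with Bron-Kerbosch (via
#' [igraph::max_cliques()]) on the thresholded distance matrix.
#'
#' Distances are measured in the full parent graph, not within the candidate
#' subset, so two genes joined only through genes outside the region still
#' count as close.  Regions are indexed deterministically: maximal sets are
#' sorted by size (descending) then by their lexicographic gene list before
#' `_1, _2, ...` suffixes are assigned.
#'
#' @param g A [pathway_graph()].
#' @param k Maximum shortest-path distance between any two member genes
#'   (default 3, the conventional subpathway-mining setting).
#' @return List of [subpathway_graph()] objects (no miRNAs embedded yet),
#'   each carrying the parent pathway edges induced on its members.
#' @export
extract_k_clique_subpathways <- function(g, k = 3) {
  stopifnot(inherits(g, "pathway_graph"), k >= 1)
  if (length(g$nodes) == 0L) return(list())
  ig <- pathway_igraph(g)
  D <- igraph::distances(ig)
  B <- is.finite(D) & D <= k
  diag(B) <- FALSE
  power <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  cliques <- igraph::max_cliques(power, min = 1L)
  sets <- lapply(cliques, function(v) sort(igraph::V(power)$name[v]))
  keys <- vapply(sets, paste, character(1L), collapse = "\r")
  o <- order(-lengths(sets), keys)
  sets <- sets[o]
  lapply(seq_along(sets), function(i) {
    members <- sets[[i]]
    keep <- g$edges[, 1L] %in% members & g$edges[, 2L] %in% members
    subpathway_graph(
      subpathway_id = sprintf("%s_%d", g$pathway_id, i),
      parent_pathway = g$pathway_id,
      genes = members,
      gene_edges = g$edges[keep, , drop = FALSE]
    )
  })
}

#' Embed miRNAs into a subpathway from a curated interaction table
#'
#' Every miRNA with at least one interaction (passing the evidence filter) to
#' a member gene is added to the subpathway; only edges to member genes are
#' recorded.  The operation is idempotent: re-embedding with the same table
#' leaves the subpathway unchanged.
#'
#' @param sub A [subpathway_graph()].
#' @param tbl Interaction table: data frame with columns `mirna`, `gene`,
#'   `evidence`.
#' @param evidence_filter Evidence classes to accept; defaults to
#'   experimentally confirmed low-throughput interactions only.
#' @return The subpathway with miRNAs and miRNA-gene edges added.
#' @export
embed_mirnas <- function(sub, tbl, evidence_filter = "low-throughput") {
  stopifnot(inherits(sub, "subpathway_graph"))
  tbl <- validate_interactions(tbl)
  keep <- tbl$evidence %in% evidence_filter & tbl$gene %in% sub$genes
  new_edges <- cbind(mirna = tbl$mirna[keep], gene = tbl$gene[keep])
  subpathway_graph(
    subpathway_id = sub$subpathway_id,
    parent_pathway = sub$parent_pathway,
    genes = sub$genes,
    mirna_gene_edges = rbind(sub$mirna_gene_edges, new_edges),
    gene_edges = sub$gene_edges
  )
}

#' Drop small subpathways
#'
#' Keeps subpathways with at least `min_mirnas` embedded miRNAs and at least
#' `min_genes` member genes; order is preserved.
#'
#' @param subs List of [subpathway_graph()] objects.
#' @param min_mirnas,min_genes Minimum component counts (defaults 1 and 3).
#' @return Filtered list.
#' @export
filter_subpathways <- function(subs, min_mirnas = 1, min_genes = 3) {
  keep <- vapply(subs, function(s) {
    length(s$mirnas) >= min_mirnas && length(s$genes) >= min_genes
  }, logical(1L))
  subs[keep]
}

#' Build filtered, miRNA-embedded subpathways for a set of pathways
#'
#' Convenience composition of [extract_k_clique_subpathways()],
#' [embed_mirnas()] and [filter_subpathways()] over a pathway list.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param interactions Interaction table (`mirna`, `gene`, `evidence`).
#' @param k Distance bound for region extraction.
#' @param min_mirnas,min_genes Size filter.
#' @param evidence_filter Evidence classes accepted for embedding.
#' @return List of [subpathway_graph()] objects.
#' @export
build_subpathways <- function(pathways, interactions, k = 3,
                              min_mirnas = 1, min_genes = 3,
                              evidence_filter = "low-throughput") {
  subs <- unlist(lapply(pathways, extract_k_clique_subpathways, k = k),
                 recursive = FALSE)
  subs <- lapply(subs, embed_mirnas, tbl = interactions,
                 evidence_filter = evidence_filter)
  filter_subpathways(subs, min_mirnas = min_mirnas, min_genes = min_genes)
}

validate_interactions <- function(tbl) {
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  req <- c("mirna", "gene", "evidence")
  missing <- setdiff(req, names(tbl))
  if (length(missing)) {
    stop("interaction table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(tbl$evidence), c("low-throughput", "high-throughput"))
  if (length(bad)) {
    stop("unknown evidence class: ", paste(bad, collapse = ", "))
  }
  tbl <- tbl[!duplicated(tbl[c("mirna", "gene")]), req, drop = FALSE]
  tbl
}
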