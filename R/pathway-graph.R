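#' Pathway and subpathway graph containers
#'
#' A `pathway_graph` is an undirected gene-level graph of one biological
#' pathway: nodes are gene identifiers, edges are (collapsed, unlabeled)
#' pathway relations.  A `subpathway_graph` is an extracted pathway region
#' together with its embedded miRNAs and miRNA-to-gene edges.
#'
#' @param pathway_id Character scalar, e.g. `"04110"`.
#' @param pathway_name Character scalar; free-text pathway title.
#' @param nodes Character vector of gene ids.
#' @param edges Two-column character matrix of unordered gene-id pairs.
#'   Self-loops are dropped; duplicate pairs are collapsed.
#' @return An object of class `pathway_graph` with elements `pathway_id`,
#'   `pathway_name`, `nodes` (sorted) and `edges` (canonicalised matrix).
#' @export
pathway_graph <- function(pathway_id, pathway_name = pathway_id,
                          nodes = character(), edges = empty_edges()) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  nodes <- sort(unique(as.character(nodes)))
  edges <- canonical_edges(edges)
  if (nrow(edges)) {
    missing <- setdiff(c(edges), nodes)
    if (length(missing)) {
      stop("edges reference unknown nodes: ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(pathway_id = pathway_id, pathway_name = pathway_name,
         nodes = nodes, edges = edges),
    class = "pathway_graph"
  )
}

empty_edges <- function() {
  matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

# Canonicalise an undirected edge list: order within pairs, drop self-loops
# and duplicates, sort rows.
canonical_edges <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) return(empty_edges())
  if (ncol(edges) != 2L) stop("edges must have two columns")
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  o <- order(a, b)
  m <- cbind(from = a[o], to = b[o])
  if (is.null(dim(m))) m <- matrix(m, ncol = 2L, dimnames = list(NULL, c("from", "to")))
  m
}

#' @rdname pathway_graph
#' @param subpathway_id Character scalar, `"<pathway_id>_<index>"`.
#' @param parent_pathway Id of the pathway the region was extracted from.
#' @param genes Member gene ids.
#' @param mirnas Embedded miRNA ids (each must have at least one edge to a
#'   member gene).
#' @param mirna_gene_edges Two-column character matrix `(mirna, gene)`.
#' @param gene_edges Pathway edges induced on the member genes.
#' @export
subpathway_graph <- function(subpathway_id, parent_pathway, genes,
                             mirnas = character(),
                             mirna_gene_edges = empty_mirna_edges(),
                             gene_edges = empty_edges()) {
  genes <- sort(unique(as.character(genes)))
  mirna_gene_edges <- canonical_mirna_edges(mirna_gene_edges)
  if (nrow(mirna_gene_edges)) {
    bad <- setdiff(mirna_gene_edges[, "gene"], genes)
    if (length(bad)) {
      stop("miRNA edges target non-member genes: ", paste(bad, collapse = ", "))
    }
  }
  mirnas <- sort(unique(c(as.character(mirnas), mirna_gene_edges[, "mirna"])))
  dangling <- setdiff(mirnas, mirna_gene_edges[, "mirna"])
  if (length(dangling)) {
    stop("miRNAs without any edge to a member gene: ",
         paste(dangling, collapse = ", "))
  }
  structure(
    list(subpathway_id = subpathway_id, parent_pathway = parent_pathway,
         genes = genes, mirnas = mirnas,
         mirna_gene_edges = mirna_gene_edges,
         gene_edges = canonical_edges(gene_edges)),
    class = "subpathway_graph"
  )
}

empty_mirna_edges <- function() {
  matrix(character(), ncol = 2L, dimnames = list(NULL, c("mirna", "gene")))
}

canonical_mirna_edges <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) return(empty_mirna_edges())
  if (ncol(edges) != 2L) stop("mirna_gene_edges must have two columns")
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("mirna", "gene")
  edges
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph %s: %d genes, %d edges>\n",
              x$pathway_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
print.subpathway_graph <- function(x, ...) {
  cat(sprintf("<subpathway %s: %d genes, %d miRNAs, %d gene edges, %d miRNA edges>\n",
              x$subpathway_id, length(x$genes), length(x$mirnas),
              nrow(x$gene_edges), nrow(x$mirna_gene_edges)))
  invisible(x)
}

# igraph view of a pathway graph (isolated nodes preserved).
pathway_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(g$edges))
  }
  ig
}
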