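#' Parse a KGML pathway file into a gene-level graph
#'
#' Reads the KEGG Markup Language (KGML) XML exchange format.  Entries of
#' type `"gene"` become nodes; `relation` elements between two gene entries
#' become undirected edges.  Group, compound and map entries are dropped.
#' An entry listing several genes (a KEGG node collapsing paralogues) is
#' expanded to all member genes with a clique among them, and any relation
#' touching the entry connects every member.
#'
#' Relation subtypes and directionality are collapsed to plain undirected
#' edges: downstream statistics use membership and distance only.
#'
#' @param path Path to a KGML file (or anything [xml2::read_xml()] accepts).
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed KGML (", paste(format(path), collapse = ""), "): ",
         conditionMessage(e), call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) stop("not a KGML document: no <pathway> root")
  pid <- xml2::xml_attr(root, "number")
  if (is.na(pid)) {
    nm <- xml2::xml_attr(root, "name")
    pid <- gsub("[^0-9]", "", if (is.na(nm)) "" else nm)
  }
  if (is.na(pid) || !nzchar(pid)) pid <- "unknown"
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- pid

  entries <- xml2::xml_find_all(doc, "/pathway/entry[@type='gene']")
  entry_ids <- xml2::xml_attr(entries, "id")
  entry_genes <- lapply(xml2::xml_attr(entries, "name"), function(nm) {
    if (is.na(nm)) character() else strsplit(trimws(nm), "\\s+")[[1L]]
  })
  names(entry_genes) <- entry_ids
  nodes <- unique(unlist(entry_genes))

  edge_rows <- list()
  # internal clique for multi-gene entries
  for (gs in entry_genes) {
    if (length(gs) >= 2L) {
      edge_rows[[length(edge_rows) + 1L]] <- t(utils::combn(gs, 2L))
    }
  }
  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  for (rel in rels) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    g1 <- entry_genes[[e1]]
    g2 <- entry_genes[[e2]]
    if (is.null(g1) || is.null(g2) || !length(g1) || !length(g2)) next
    edge_rows[[length(edge_rows) + 1L]] <-
      cbind(rep(g1, times = length(g2)), rep(g2, each = length(g1)))
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else empty_edges()
  pathway_graph(pathway_id = pid, pathway_name = title,
                nodes = nodes, edges = edges)
}
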