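#' Read an expression matrix from TSV
#'
#' Expected layout: header row of sample ids, first column feature ids,
#' non-negative FPKM-like values.  Duplicate-sample columns are resolved by
#' averaging; duplicate feature rows are an error.
#'
#' @param path TSV file path.
#' @return Numeric matrix, features x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(df[[1L]])
  if (anyDuplicated(feats)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  colnames(m) <- names(df)[-1L]  # as.matrix mangles duplicated sample ids
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  if (any(m < 0)) stop("negative expression values in ", path)
  if (anyDuplicated(colnames(m))) {
    m <- average_duplicate_samples(m)
  }
  m
}

# Average expression over duplicated sample columns.
average_duplicate_samples <- function(m) {
  ids <- colnames(m)
  uniq <- unique(ids)
  out <- vapply(uniq, function(s) {
    rowMeans(m[, ids == s, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), uniq))
  out
}

#' @rdname read_expression_tsv
#' @param m Numeric feature-by-sample matrix.
#' @param feature_col Name used for the first (feature id) column.
#' @export
write_expression_tsv <- function(m, path, feature_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Columns: `sample_id`, `time_months` (non-negative, finite), `event`
#' (0 = censored, 1 = event).  Sample ids must be unique.
#'
#' @param path TSV file path.
#' @return data.frame with the three validated columns.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical_tsv
#' @param clin Clinical data frame.
#' @export
write_clinical_tsv <- function(clin, path) {
  utils::write.table(validate_clinical(clin), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_clinical <- function(clin) {
  req <- c("sample_id", "time_months", "event")
  missing <- setdiff(req, names(clin))
  if (length(missing)) {
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  }
  clin <- as.data.frame(clin)[req]
  clin$sample_id <- as.character(clin$sample_id)
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(!is.finite(clin$time_months)) || any(clin$time_months < 0)) {
    stop("survival times must be finite and non-negative")
  }
  if (!all(clin$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  clin$event <- as.integer(clin$event)
  rownames(clin) <- NULL
  clin
}

#' Read / write a miRNA-gene interaction table
#'
#' Columns: `mirna`, `gene`, `evidence` (`low-throughput` or
#' `high-throughput`).  Duplicate (mirna, gene) pairs are collapsed to the
#' first occurrence.
#'
#' @param path TSV file path.
#' @return Validated data frame.
#' @export
read_interactions_tsv <- function(path) {
  validate_interactions(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_interactions_tsv
#' @param tbl Interaction data frame.
#' @export
write_interactions_tsv <- function(tbl, path) {
  utils::write.table(validate_interactions(tbl), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize subpathways to JSON and back
#'
#' The JSON form records, per subpathway: id, parent pathway, gene list,
#' miRNA list, gene-gene edges and miRNA-gene edges.
#'
#' @param subs List of [subpathway_graph()] objects.
#' @param path Output JSON path.
#' @export
write_subpathways_json <- function(subs, path) {
  payload <- lapply(subs, function(s) {
    list(
      subpathway_id = s$subpathway_id,
      parent_pathway = s$parent_pathway,
      genes = as.list(s$genes),
      mirnas = as.list(s$mirnas),
      gene_edges = apply(s$gene_edges, 1L, as.list, simplify = FALSE),
      mirna_gene_edges = apply(s$mirna_gene_edges, 1L, as.list, simplify = FALSE)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_subpathways_json
#' @return `read_subpathways_json()` returns a list of [subpathway_graph()].
#' @export
read_subpathways_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p) {
    subpathway_graph(
      subpathway_id = p$subpathway_id,
      parent_pathway = p$parent_pathway,
      genes = unlist(p$genes),
      mirna_gene_edges = edges_from_json(p$mirna_gene_edges, c("mirna", "gene")),
      gene_edges = edges_from_json(p$gene_edges, c("from", "to"))
    )
  })
}

edges_from_json <- function(x, cols) {
  if (!length(x)) {
    m <- matrix(character(), ncol = 2L)
  } else {
    m <- do.call(rbind, lapply(x, function(e) unlist(e, use.names = FALSE)))
  }
  colnames(m) <- cols
  m
}

#' Export a subpathway as GraphML for visualization
#'
#' Genes and miRNAs become typed nodes (`node_type` attribute); both gene-gene
#' and miRNA-gene edges are included.
#'
#' @param sub A [subpathway_graph()].
#' @param path Output GraphML path.
#' @export
write_subpathway_graphml <- function(sub, path) {
  nodes <- c(sub$genes, sub$mirnas)
  ig <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = nodes)
  ig <- igraph::set_vertex_attr(
    ig, "node_type",
    value = rep(c("gene", "mirna"), c(length(sub$genes), length(sub$mirnas)))
  )
  edges <- rbind(unname(sub$gene_edges), unname(sub$mirna_gene_edges))
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
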