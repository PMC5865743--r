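#' Repeat the screen + enrichment stages over resampled training subsets
#'
#' For each subset, features are re-screened with univariate Cox models and
#' every subpathway is re-tested with the pooled hypergeometric statistic.
#' Per-subset call tables can be cached to disk (one TSV per subset, subset
#' index in the filename) so interrupted runs resume.
#'
#' @param subsets List of sample-id vectors from [make_training_subsets()].
#' @param mirna_expr,gene_expr Expression matrices covering all subset
#'   samples.
#' @param clin Clinical data frame.
#' @param subpathways List of [subpathway_graph()] objects.
#' @param alpha_feature Cox screening level (default 0.05).
#' @param alpha_subpathway Subpathway call level (default 0.05).
#' @param transform Covariate transform for the Cox screen.
#' @param cache_dir Optional directory for per-subset result caching.
#' @return List of per-subset call data.frames (see
#'   [identify_survival_subpathways()]).
#' @export
run_resampled_screens <- function(subsets, mirna_expr, gene_expr, clin,
                                  subpathways, alpha_feature = 0.05,
                                  alpha_subpathway = 0.05,
                                  transform = c("log2z", "none"),
                                  cache_dir = NULL) {
  transform <- match.arg(transform)
  clin <- validate_clinical(clin)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  lapply(seq_along(subsets), function(b) {
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, sprintf("subset_%04d.tsv", b))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      return(utils::read.delim(cache_file, stringsAsFactors = FALSE))
    }
    ids <- subsets[[b]]
    clin_b <- clin[clin$sample_id %in% ids, , drop = FALSE]
    scr <- screen_features(mirna_expr[, clin_b$sample_id, drop = FALSE],
                           gene_expr[, clin_b$sample_id, drop = FALSE],
                           clin_b, alpha = alpha_feature,
                           transform = transform)
    calls <- identify_survival_subpathways(
      subpathways, scr$survival_genes, scr$survival_mirnas, scr$universe,
      measured_genes = rownames(gene_expr),
      measured_mirnas = rownames(mirna_expr),
      alpha = alpha_subpathway
    )
    if (!is.null(cache_file)) {
      utils::write.table(calls, cache_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    calls
  })
}

#' Robustness counts and ranks over resampled subpathway calls
#'
#' A subpathway's count is the number of subsets in which it was called
#' significant; subpathways with higher counts are more robust.  Ranks are
#' dense on the count (1 = highest); row order and count ties are resolved
#' by mean p-value (ascending) then id.
#'
#' @param lists List of per-subset call data.frames.
#' @return data.frame (`subpathway_id`, `count`, `mean_p`, `rank`).
#' @export
count_subpathway_hits <- function(lists) {
  stopifnot(length(lists) > 0L)
  all_calls <- do.call(rbind, lists)
  n_lists <- length(lists)
  counts <- vapply(split(all_calls$significant, all_calls$subpathway_id),
                   sum, numeric(1L))
  tab <- data.frame(
    subpathway_id = names(counts),
    count = as.integer(counts),
    mean_p = vapply(split(all_calls$p_value, all_calls$subpathway_id),
                    mean, numeric(1L)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$count, tab$mean_p, tab$subpathway_id), , drop = FALSE]
  tab$rank <- match(tab$count, sort(unique(tab$count), decreasing = TRUE))
  rownames(tab) <- NULL
  stopifnot(all(tab$count <= n_lists))
  tab
}

#' Select robust subpathways from the ranked table
#'
#' @param table Robustness table from [count_subpathway_hits()].
#' @param mode `"top_n"` keeps all subpathways with dense rank at most
#'   `value` (the default selection); `"min_count"` keeps those significant
#'   in at least `value` subsets.
#' @param value Positive selection threshold.
#' @return Character vector of subpathway ids, in table order.
#' @export
select_robust <- function(table, mode = c("top_n", "min_count"), value = 3) {
  mode <- match.arg(mode)
  stopifnot(value >= 1)
  keep <- switch(mode,
    top_n = table$rank <= value,
    min_count = table$count >= value
  )
  table$subpathway_id[keep]
}
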