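#' Counts feeding the pooled gene+miRNA hypergeometric test
#'
#' The urn pools genes and miRNAs: the population holds all `m_g` measured
#' genes and `m_mir` measured miRNAs, the subpathway marks `t_g + t_mir` of
#' them, and the `n_g + n_mir` survival-associated features are the draw.
#' `r_g`/`r_mir` count survival features that fall inside the subpathway.
#'
#' @param m_g,m_mir Numbers of all measured genes / miRNAs.
#' @param n_g,n_mir Numbers of survival genes / miRNAs.
#' @param t_g,t_mir Numbers of subpathway genes / miRNAs (measured only).
#' @param r_g,r_mir Survival genes / miRNAs inside the subpathway.
#' @return Validated list of class `hypergeom_inputs`.
#' @export
hypergeom_inputs <- function(m_g, m_mir, n_g, n_mir, t_g, t_mir, r_g, r_mir) {
  h <- list(m_g = as.integer(m_g), m_mir = as.integer(m_mir),
            n_g = as.integer(n_g), n_mir = as.integer(n_mir),
            t_g = as.integer(t_g), t_mir = as.integer(t_mir),
            r_g = as.integer(r_g), r_mir = as.integer(r_mir))
  for (f in names(h)) {
    if (is.na(h[[f]]) || h[[f]] < 0L) stop("count ", f, " must be >= 0")
  }
  check <- function(cond, msg) if (!cond) stop("invalid counts: ", msg)
  check(h$n_g <= h$m_g, "n_g exceeds m_g")
  check(h$n_mir <= h$m_mir, "n_mir exceeds m_mir")
  check(h$t_g <= h$m_g, "t_g exceeds m_g")
  check(h$t_mir <= h$m_mir, "t_mir exceeds m_mir")
  check(h$r_g <= min(h$n_g, h$t_g), "r_g exceeds min(n_g, t_g)")
  check(h$r_mir <= min(h$n_mir, h$t_mir), "r_mir exceeds min(n_mir, t_mir)")
  structure(h, class = "hypergeom_inputs")
}

#' Upper-tail probability of the pooled hypergeometric statistic
#'
#' With `N = m_g + m_mir` features in the urn, `K = t_g + t_mir` of them in
#' the subpathway and `n = n_g + n_mir` survival features drawn, returns
#' `P(X >= r_g + r_mir)` for `X ~ Hypergeom(N, K, n)` — equivalently
#' `1 - sum_{k < r} C(K,k) C(N-K, n-k) / C(N,n)`.  Computed with
#' [stats::phyper()] (log-space stable) and clamped to `[0, 1]`.  When the
#' subpathway marks nothing or nothing is drawn (or the observed overlap is
#' zero) there is no evidence and the p-value is exactly 1.
#'
#' @param h A [hypergeom_inputs()] object (or arguments to build one).
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(h) {
  if (!inherits(h, "hypergeom_inputs")) h <- do.call(hypergeom_inputs, as.list(h))
  r <- h$r_g + h$r_mir
  K <- h$t_g + h$t_mir
  n <- h$n_g + h$n_mir
  N <- h$m_g + h$m_mir
  if (r == 0L || K == 0L || n == 0L) return(1)
  p <- stats::phyper(r - 1L, K, N - K, n, lower.tail = FALSE)
  min(max(p, 0), 1)
}

#' Count subpathway overlaps with survival feature sets
#'
#' Members absent from the measured universe are excluded from every count,
#' keeping the urn model coherent (the urn is the measured data, not the
#' pathway database).
#'
#' @param sub A [subpathway_graph()].
#' @param survival_genes,survival_mirnas Screened survival feature sets
#'   (must lie inside the measured universe).
#' @param universe Named vector or list with `m_g` and `m_mir`.
#' @param measured_genes,measured_mirnas Ids of measured features.
#' @return A [hypergeom_inputs()] object.
#' @export
tally_overlaps <- function(sub, survival_genes, survival_mirnas, universe,
                           measured_genes, measured_mirnas) {
  if (!all(survival_genes %in% measured_genes) ||
      !all(survival_mirnas %in% measured_mirnas)) {
    stop("survival sets must be subsets of the measured features")
  }
  tg <- intersect(sub$genes, measured_genes)
  tm <- intersect(sub$mirnas, measured_mirnas)
  hypergeom_inputs(
    m_g = universe[["m_g"]], m_mir = universe[["m_mir"]],
    n_g = length(survival_genes), n_mir = length(survival_mirnas),
    t_g = length(tg), t_mir = length(tm),
    r_g = length(intersect(tg, survival_genes)),
    r_mir = length(intersect(tm, survival_mirnas))
  )
}

#' Call survival-related subpathways
#'
#' Applies the pooled hypergeometric test to every subpathway and flags
#' those with p below `alpha`.  Selection is on raw p-values (the screening
#' convention this statistic was designed around); a Benjamini-Hochberg FDR
#' column is included for information only.
#'
#' @param subs List of [subpathway_graph()] objects.
#' @param survival_genes,survival_mirnas Screened survival feature sets.
#' @param universe Named vector/list with `m_g`, `m_mir`.
#' @param measured_genes,measured_mirnas Measured feature ids.
#' @param alpha Significance level (default 0.05).
#' @return data.frame ordered by ascending p (ties by id) with columns
#'   `subpathway_id`, `p_value`, `bh_fdr`, the eight counts, `significant`.
#' @export
identify_survival_subpathways <- function(subs, survival_genes,
                                          survival_mirnas, universe,
                                          measured_genes, measured_mirnas,
                                          alpha = 0.05) {
  rows <- lapply(subs, function(s) {
    h <- tally_overlaps(s, survival_genes, survival_mirnas, universe,
                        measured_genes, measured_mirnas)
    data.frame(subpathway_id = s$subpathway_id,
               p_value = hypergeom_pvalue(h),
               r_g = h$r_g, r_mir = h$r_mir, t_g = h$t_g, t_mir = h$t_mir,
               n_g = h$n_g, n_mir = h$n_mir, m_g = h$m_g, m_mir = h$m_mir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subpathway_id = character(), p_value = numeric(),
                      r_g = integer(), r_mir = integer(), t_g = integer(),
                      t_mir = integer(), n_g = integer(), n_mir = integer(),
                      m_g = integer(), m_mir = integer())
  }
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$subpathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
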