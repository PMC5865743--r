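#' Drop samples with very short follow-up
#'
#' Samples with survival time below `min_months` are removed before any
#' analysis: in a leukemia cohort, deaths inside the first month are likely
#' unrelated to the disease course under study.  The boundary itself is
#' kept (strictly-less-than removal).
#'
#' @param clin Clinical data frame (`sample_id`, `time_months`, `event`).
#' @param min_months Removal threshold in months (default 1).
#' @return Filtered clinical table; the number of removed samples is
#'   reported with [message()].
#' @export
exclude_short_survivors <- function(clin, min_months = 1) {
  clin <- validate_clinical(clin)
  keep <- clin$time_months >= min_months
  message(sum(!keep), " sample(s) removed with survival time < ",
          min_months, " month(s)")
  out <- clin[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Good/poor survival strata at the median
#'
#' Samples with observed time below the cohort median are "poor", the rest
#' "good".  Censored samples are classified by their observed (censored)
#' time — the simplest reproducible reading of a median-time stratification.
#'
#' @param clin Clinical data frame.
#' @return Named character vector (`sample_id` -> `"good"`/`"poor"`).
#' @export
median_survival_strata <- function(clin) {
  clin <- validate_clinical(clin)
  if (nrow(clin) < 2L) stop("need at least 2 samples to stratify")
  med <- stats::median(clin$time_months)
  strata <- ifelse(clin$time_months < med, "poor", "good")
  names(strata) <- clin$sample_id
  strata
}

# Stratified sample of ids at `frac`, largest-remainder rounding with total
# target ceiling(frac * n).  Consumes the current RNG stream.
stratified_sample_ids <- function(ids, strata, frac) {
  strata <- strata[ids]
  total <- ceiling(frac * length(ids))
  groups <- split(ids, strata)
  groups <- groups[order(names(groups))]
  quota <- vapply(groups, length, integer(1L)) * frac
  take <- floor(quota)
  rem <- total - sum(take)
  if (rem > 0L) {
    o <- order(-(quota - take), names(groups))
    bump <- o[seq_len(rem)]
    take[bump] <- take[bump] + 1L
  }
  take <- pmin(take, vapply(groups, length, integer(1L)))
  picked <- unlist(lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (take[i] >= length(g)) g else sample(g, take[i])
  }), use.names = FALSE)
  sort(picked)
}

#' Stratified train/test split
#'
#' Allocates samples to a training set at `train_frac` within each
#' good/poor survival stratum (largest-remainder rounding), so both sets
#' keep the cohort's ratio of good and poor survivors.  The default
#' fraction mirrors a 76/112 training share.
#'
#' @param clin Clinical data frame.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(clin, train_frac = 76 / 112, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  clin <- validate_clinical(clin)
  strata <- median_survival_strata(clin)
  set.seed(as.integer(seed))
  train <- stratified_sample_ids(clin$sample_id, strata, train_frac)
  list(train = train, test = sort(setdiff(clin$sample_id, train)))
}

#' Resampled stratified training subsets
#'
#' Draws `n_subsets` independent stratified subsets of the training set,
#' each containing `frac` of the training samples (without replacement
#' within a subset) and preserving the good/poor ratio of the full
#' training set.
#'
#' @param train_ids Character vector of training sample ids.
#' @param strata Named stratum vector covering `train_ids`.
#' @param n_subsets Number of subsets (default 100).
#' @param frac Fraction per subset (default 0.5).
#' @param seed Integer seed.
#' @return List of `n_subsets` character vectors.
#' @export
make_training_subsets <- function(train_ids, strata, n_subsets = 100,
                                  frac = 0.5, seed = 1L) {
  stopifnot(n_subsets >= 1, frac > 0, frac <= 1)
  set.seed(as.integer(seed))
  lapply(seq_len(n_subsets), function(b) {
    stratified_sample_ids(train_ids, strata, frac)
  })
}

#' Univariate Cox proportional-hazards fit for one feature
#'
#' Fits a single-covariate Cox model by partial likelihood (Efron tie
#' handling) and reports the Wald test.  By default the covariate is
#' transformed as standardized log2(x + 1), the scale used throughout the
#' screening and risk-scoring stages.  Zero-variance covariates are flagged
#' `degenerate` (p = 1 by convention, not fitted); fits that do not converge
#' or run away (monotone likelihood) are flagged `nonconverged` and excluded
#' from screening.
#'
#' @param x Named numeric vector of expression values (names = sample ids).
#' @param clin Clinical data frame covering those samples.
#' @param transform One of `"log2z"` (default) or `"none"`.
#' @param feature_id Optional id copied into the result.
#' @return List of class `cox_result`: `feature_id`, `coefficient`, `se`,
#'   `p_value`, `status` (`ok`, `degenerate`, `nonconverged`).
#' @export
cox_univariate <- function(x, clin, transform = c("log2z", "none"),
                           feature_id = NA_character_) {
  transform <- match.arg(transform)
  clin <- validate_clinical(clin)
  if (is.null(names(x))) {
    if (length(x) != nrow(clin)) stop("unnamed covariate of wrong length")
    names(x) <- clin$sample_id
  }
  if (!all(clin$sample_id %in% names(x))) {
    stop("covariate does not cover all clinical samples")
  }
  x <- x[clin$sample_id]
  y <- survival::Surv(clin$time_months, clin$event)
  cox_fit_one(x, y, transform = transform, feature_id = feature_id)
}

# Core single-covariate fit against a prebuilt Surv object (fast path used
# by the screening loops).
cox_fit_one <- function(x, y, transform = "log2z",
                        feature_id = NA_character_) {
  if (transform == "log2z") {
    x <- log2(x + 1)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      return(cox_result(feature_id, status = "degenerate"))
    }
    x <- (x - mean(x)) / s
  } else if (stats::sd(x) == 0) {
    return(cox_result(feature_id, status = "degenerate"))
  }
  ctrl <- survival::coxph.control()
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(matrix(x, ncol = 1L), y, strata = NULL,
                          offset = NULL, init = 0, control = ctrl,
                          weights = NULL, method = "efron", rownames = NULL)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(cox_result(feature_id, status = "nonconverged"))
  beta <- unname(fit$coefficients)
  v <- as.numeric(fit$var)
  if (!is.finite(beta) || !is.finite(v) || v <= 0 ||
      abs(beta) > 15 || fit$iter >= ctrl$iter.max) {
    return(cox_result(feature_id, status = "nonconverged"))
  }
  se <- sqrt(v)
  z <- beta / se
  cox_result(feature_id, coefficient = beta, se = se,
             p_value = 2 * stats::pnorm(-abs(z)), status = "ok")
}

cox_result <- function(feature_id, coefficient = NA_real_, se = NA_real_,
                       p_value = if (identical(status, "degenerate")) 1 else NA_real_,
                       status = "ok") {
  structure(
    list(feature_id = feature_id, coefficient = coefficient, se = se,
         p_value = p_value, status = status),
    class = "cox_result"
  )
}

#' Screen miRNAs and genes for survival association
#'
#' Runs [cox_univariate()] over every feature of both expression matrices
#' and selects features with an `ok` fit and Wald p-value below `alpha`.
#' No multiple-testing correction is applied at this step: selection on raw
#' p-values is the screening rule the downstream enrichment statistic is
#' built around.
#'
#' @param mirna_expr,gene_expr Feature-by-sample matrices covering the
#'   clinical samples.
#' @param clin Clinical data frame.
#' @param alpha Screening level (default 0.05).
#' @param transform Covariate transform, as in [cox_univariate()].
#' @return List: `survival_mirnas`, `survival_genes` (character vectors),
#'   `results` (one data.frame over all features), `universe`
#'   (`m_g`, `m_mir` — numbers of measured genes and miRNAs).
#' @export
screen_features <- function(mirna_expr, gene_expr, clin, alpha = 0.05,
                            transform = c("log2z", "none")) {
  transform <- match.arg(transform)
  clin <- validate_clinical(clin)
  for (m in list(mirna_expr, gene_expr)) {
    if (!all(clin$sample_id %in% colnames(m))) {
      stop("expression matrix does not cover all clinical samples")
    }
  }
  y <- survival::Surv(clin$time_months, clin$event)
  screen_one <- function(expr) {
    expr <- expr[, clin$sample_id, drop = FALSE]
    res <- lapply(rownames(expr), function(f) {
      cox_fit_one(expr[f, ], y, transform = transform, feature_id = f)
    })
    data.frame(
      feature_id = vapply(res, `[[`, character(1L), "feature_id"),
      coefficient = vapply(res, `[[`, numeric(1L), "coefficient"),
      se = vapply(res, `[[`, numeric(1L), "se"),
      p_value = vapply(res, `[[`, numeric(1L), "p_value"),
      status = vapply(res, `[[`, character(1L), "status"),
      stringsAsFactors = FALSE
    )
  }
  res_mir <- screen_one(mirna_expr)
  res_gene <- screen_one(gene_expr)
  res_mir$kind <- "miRNA"
  res_gene$kind <- "gene"
  sel <- function(res) {
    res$feature_id[res$status == "ok" & res$p_value < alpha]
  }
  list(
    survival_mirnas = sel(res_mir),
    survival_genes = sel(res_gene),
    results = rbind(res_gene, res_mir),
    universe = c(m_g = nrow(gene_expr), m_mir = nrow(mirna_expr))
  )
}
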