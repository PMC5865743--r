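#' Fit a subpathway risk-score model on the training set
#'
#' The risk score is a linear combination of every measured miRNA and gene
#' in the subpathway — significant or not — each weighted by its univariate
#' Cox coefficient refit on the full training set.  Covariates use the same
#' transform as the screen (standardized log2(FPKM+1) by default), with the
#' centering and scaling parameters frozen from the training samples so
#' test-set scores live on the training scale.  Components whose training
#' fit is degenerate or does not converge get weight 0 and are flagged.
#'
#' @param sub A [subpathway_graph()].
#' @param mirna_expr,gene_expr Expression matrices (must cover the training
#'   samples; at least one subpathway member must be measured).
#' @param clin_train Training clinical data frame.
#' @param transform `"log2z"` (default) or `"none"`.
#' @return Object of class `risk_score_model`: `subpathway_id`,
#'   `components` (data.frame `feature_id`, `kind`, `weight`, `center`,
#'   `scale`, `flagged`), `transform`, `training_median`.
#' @export
fit_risk_model <- function(sub, mirna_expr, gene_expr, clin_train,
                           transform = c("log2z", "none")) {
  transform <- match.arg(transform)
  clin_train <- validate_clinical(clin_train)
  genes <- intersect(sub$genes, rownames(gene_expr))
  mirs <- intersect(sub$mirnas, rownames(mirna_expr))
  if (length(genes) + length(mirs) == 0L) {
    stop("subpathway ", sub$subpathway_id, " has no measured members")
  }
  y <- survival::Surv(clin_train$time_months, clin_train$event)
  comp_one <- function(f, kind) {
    expr <- if (kind == "gene") gene_expr else mirna_expr
    x <- expr[f, clin_train$sample_id]
    if (transform == "log2z") {
      lx <- log2(x + 1)
      ctr <- mean(lx); scl <- stats::sd(lx)
    } else {
      ctr <- 0; scl <- 1
    }
    fit <- cox_fit_one(x, y, transform = transform, feature_id = f)
    flagged <- fit$status != "ok"
    data.frame(feature_id = f, kind = kind,
               weight = if (flagged) 0 else fit$coefficient,
               center = ctr,
               scale = if (is.finite(scl) && scl > 0) scl else 1,
               flagged = flagged, stringsAsFactors = FALSE)
  }
  components <- rbind(
    do.call(rbind, lapply(genes, comp_one, kind = "gene")),
    do.call(rbind, lapply(mirs, comp_one, kind = "miRNA"))
  )
  rownames(components) <- NULL
  if (all(components$flagged)) {
    stop("no usable components in subpathway ", sub$subpathway_id)
  }
  model <- structure(
    list(subpathway_id = sub$subpathway_id, components = components,
         transform = transform, training_median = NA_real_),
    class = "risk_score_model"
  )
  model$training_median <- stats::median(
    score_samples(model, mirna_expr[, clin_train$sample_id, drop = FALSE],
                  gene_expr[, clin_train$sample_id, drop = FALSE])
  )
  model
}

#' Per-sample risk scores under a fitted model
#'
#' @param model A `risk_score_model` or `combined_risk_model`.
#' @param mirna_expr,gene_expr Expression matrices; every non-degenerate
#'   component feature must be present (a missing feature is an error, never
#'   a silent drop).
#' @return Named numeric vector of scores (one per sample column).
#' @export
score_samples <- function(model, mirna_expr, gene_expr) {
  UseMethod("score_samples")
}

#' @export
score_samples.risk_score_model <- function(model, mirna_expr, gene_expr) {
  samples <- colnames(gene_expr)
  if (!identical(samples, colnames(mirna_expr))) {
    mirna_expr <- mirna_expr[, samples, drop = FALSE]
  }
  scores <- numeric(length(samples))
  names(scores) <- samples
  cm <- model$components
  for (i in seq_len(nrow(cm))) {
    if (cm$flagged[i]) next
    expr <- if (cm$kind[i] == "gene") gene_expr else mirna_expr
    if (!cm$feature_id[i] %in% rownames(expr)) {
      stop("component feature missing from expression data: ",
           cm$feature_id[i])
    }
    x <- expr[cm$feature_id[i], ]
    xt <- if (model$transform == "log2z") {
      (log2(x + 1) - cm$center[i]) / cm$scale[i]
    } else {
      x
    }
    scores <- scores + cm$weight[i] * xt
  }
  scores
}

#' @export
score_samples.combined_risk_model <- function(model, mirna_expr, gene_expr) {
  sub_scores <- vapply(model$sub_models, score_samples,
                       numeric(ncol(gene_expr)),
                       mirna_expr = mirna_expr, gene_expr = gene_expr)
  as.numeric(sub_scores %*% model$sub_weights) |>
    stats::setNames(colnames(gene_expr))
}

#' Split samples into high- and low-risk groups at a cutoff
#'
#' Scores strictly above the cutoff are `"high"`, the rest `"low"` (ties go
#' to low risk).  For a held-out cohort the cutoff should be the training
#' median, avoiding test-set leakage.
#'
#' @param scores Named numeric vector of risk scores.
#' @param cutoff Numeric cutoff (typically a training median).
#' @return Named character vector (`"high"`/`"low"`).
#' @export
dichotomize <- function(scores, cutoff) {
  out <- ifelse(scores > cutoff, "high", "low")
  names(out) <- names(scores)
  out
}

#' Combine several subpathway risk models
#'
#' Each sub-model's training risk score becomes a covariate in its own
#' univariate Cox fit on the training set; the resulting coefficients weight
#' the sub-scores in the combined linear score.
#'
#' @param models List of at least two `risk_score_model` objects.
#' @param mirna_expr,gene_expr Training expression matrices.
#' @param clin_train Training clinical data frame.
#' @return Object of class `combined_risk_model`: `sub_models`,
#'   `sub_weights`, `training_median`.
#' @export
combined_fit <- function(models, mirna_expr, gene_expr, clin_train) {
  if (length(models) < 2L) {
    stop("combined model needs at least 2 sub-models; use the single model directly")
  }
  clin_train <- validate_clinical(clin_train)
  me <- mirna_expr[, clin_train$sample_id, drop = FALSE]
  ge <- gene_expr[, clin_train$sample_id, drop = FALSE]
  y <- survival::Surv(clin_train$time_months, clin_train$event)
  weights <- vapply(models, function(m) {
    s <- score_samples(m, me, ge)
    fit <- cox_fit_one(s, y, transform = "none",
                       feature_id = m$subpathway_id)
    if (fit$status != "ok") 0 else fit$coefficient
  }, numeric(1L))
  model <- structure(
    list(sub_models = models, sub_weights = weights,
         training_median = NA_real_),
    class = "combined_risk_model"
  )
  model$training_median <- stats::median(score_samples(model, me, ge))
  model
}

#' Kaplan-Meier survival curve for a sample group
#'
#' Product-limit estimator: censored times reduce the risk set without a
#' step.
#'
#' @param sample_ids Samples in the group (at least one).
#' @param clin Clinical data frame covering them.
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (non-increasing, starts below 1 only after the
#'   first event).
#' @export
km_curve <- function(sample_ids, clin) {
  clin <- validate_clinical(clin)
  stopifnot(length(sample_ids) >= 1L)
  d <- clin[clin$sample_id %in% sample_ids, , drop = FALSE]
  if (!nrow(d)) stop("no clinical rows for the given samples")
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = d)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: summed observed-minus-expected events with
#' hypergeometric variance at each event time, referred to chi-square with
#' one degree of freedom.  P-values are floored at 1e-300 (a printed zero is
#' underflow, never an exact zero).
#'
#' @param groups Named character vector assigning each sample to one of two
#'   groups (e.g. from [dichotomize()]); both groups must be non-empty.
#' @param clin Clinical data frame covering the samples.
#' @return List: `chi2`, `p`, `n` (per-group sizes), `observed`, `expected`.
#' @export
logrank_test <- function(groups, clin) {
  clin <- validate_clinical(clin)
  d <- clin[clin$sample_id %in% names(groups), , drop = FALSE]
  d$group <- groups[d$sample_id]
  lev <- unique(d$group)
  if (length(lev) != 2L) {
    stop("log-rank test needs exactly 2 non-empty groups, got ", length(lev))
  }
  sd_ <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                            data = d)
  chi2 <- unname(sd_$chisq)
  p <- max(stats::pchisq(chi2, df = 1L, lower.tail = FALSE), 1e-300)
  list(chi2 = chi2, p = p, n = sd_$n, observed = sd_$obs, expected = sd_$exp)
}

#' Evaluate a risk model on a cohort
#'
#' Scores the cohort, dichotomizes at the supplied cutoff (training median
#' by default), and compares the two groups with Kaplan-Meier curves and the
#' log-rank test.
#'
#' @param model Risk model (single or combined).
#' @param mirna_expr,gene_expr Cohort expression matrices.
#' @param clin Cohort clinical data frame.
#' @param cutoff Risk cutoff; defaults to the model's training median.
#' @return List of class `survival_comparison`: `scores`, `groups`,
#'   `km` (per-group curves), `logrank` (`chi2`, `p`), `cutoff`.
#' @export
evaluate_risk_model <- function(model, mirna_expr, gene_expr, clin,
                                cutoff = model$training_median) {
  clin <- validate_clinical(clin)
  scores <- score_samples(model, mirna_expr[, clin$sample_id, drop = FALSE],
                          gene_expr[, clin$sample_id, drop = FALSE])
  groups <- dichotomize(scores, cutoff)
  km <- lapply(split(names(groups), groups), km_curve, clin = clin)
  lr <- if (length(unique(groups)) == 2L) {
    logrank_test(groups, clin)
  } else {
    list(chi2 = NA_real_, p = NA_real_)
  }
  structure(list(scores = scores, groups = groups, km = km, logrank = lr,
                 cutoff = cutoff),
            class = "survival_comparison")
}

#' Serialize risk models to JSON
#'
#' @param models List of `risk_score_model` objects, optionally with one
#'   `combined_risk_model` under the name `combined`.
#' @param path Output JSON path.
#' @export
write_risk_models_json <- function(models, path) {
  ser_single <- function(m) {
    list(subpathway_id = m$subpathway_id, transform = m$transform,
         training_median = m$training_median,
         components = m$components)
  }
  payload <- lapply(models, function(m) {
    if (inherits(m, "combined_risk_model")) {
      list(kind = "combined", sub_weights = m$sub_weights,
           training_median = m$training_median,
           sub_models = lapply(m$sub_models, ser_single))
    } else {
      c(list(kind = "single"), ser_single(m))
    }
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
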