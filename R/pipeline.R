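#' Pipeline configuration
#'
#' Collects every stage setting in one validated list.  Inputs are either a
#' synthetic scenario (`scenario =` a [scenario_config()]) or paths to the
#' standard TSV/JSON inputs (`mirna_expr`, `gene_expr`, `clinical`,
#' `interactions`, `pathways_dir` of KGML files or `subpathways` JSON).
#' Unknown keys are rejected.
#'
#' @param outdir Output directory for every artifact.
#' @param scenario Optional [scenario_config()]; when given, stage one
#'   simulates the inputs into `outdir/data`.
#' @param inputs Named list of input file paths (ignored when `scenario` is
#'   given): `mirna_expr`, `gene_expr`, `clinical`, `interactions`, and one
#'   of `subpathways` (JSON) or `kgml_dir`.
#' @param k,min_genes,min_mirnas Subpathway construction settings.
#' @param evidence_filter Interaction evidence classes used for embedding.
#' @param alpha_feature,alpha_subpathway Screening / enrichment levels.
#' @param min_months Short-survivor exclusion threshold (months).
#' @param train_frac Training fraction of the cohort.
#' @param n_subsets,subset_frac Resampling settings.
#' @param selection List `list(mode, value)` for [select_robust()].
#' @param transform Expression transform for Cox fits.
#' @param seed Master seed for split/subset randomness.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, scenario = NULL, inputs = NULL,
                            k = 3, min_genes = 3, min_mirnas = 1,
                            evidence_filter = "low-throughput",
                            alpha_feature = 0.05, alpha_subpathway = 0.05,
                            min_months = 1, train_frac = 76 / 112,
                            n_subsets = 100, subset_frac = 0.5,
                            selection = list(mode = "top_n", value = 3),
                            transform = "log2z", seed = 1L) {
  cfg <- list(outdir = outdir, scenario = scenario, inputs = inputs,
              k = k, min_genes = min_genes, min_mirnas = min_mirnas,
              evidence_filter = evidence_filter,
              alpha_feature = alpha_feature,
              alpha_subpathway = alpha_subpathway,
              min_months = min_months, train_frac = train_frac,
              n_subsets = as.integer(n_subsets), subset_frac = subset_frac,
              selection = selection, transform = transform,
              seed = as.integer(seed))
  if (is.null(cfg$scenario)) {
    req <- c("mirna_expr", "gene_expr", "clinical")
    missing <- setdiff(req, names(cfg$inputs))
    if (length(missing)) {
      stop("inputs lack required paths: ", paste(missing, collapse = ", "))
    }
    if (!any(c("subpathways", "kgml_dir") %in% names(cfg$inputs))) {
      stop("inputs need either 'subpathways' (JSON) or 'kgml_dir'")
    }
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) stop("input does not exist: ", p)
    }
  } else {
    stopifnot(inherits(cfg$scenario, "scenario_config"))
  }
  stopifnot(cfg$train_frac > 0, cfg$train_frac < 1,
            cfg$subset_frac > 0, cfg$subset_frac <= 1,
            cfg$n_subsets >= 1,
            cfg$selection$mode %in% c("top_n", "min_count"),
            cfg$selection$value >= 1,
            cfg$transform %in% c("log2z", "none"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full subpathway-signature workflow
#'
#' Stages: (1) simulate or load inputs; (2) build miRNA-embedded
#' subpathways; (3) exclude short survivors, stratified train/test split,
#' resampled training subsets; (4) per-subset Cox screen + pooled
#' hypergeometric calls; (5) robustness counts and selection; (6) risk-score
#' models (single per selected subpathway, plus a combined model when two or
#' more are selected) evaluated on training and held-out test cohorts.
#' Every artifact is written under `cfg$outdir` and checksummed into
#' `manifest.json`; re-running with the same config and seed reproduces the
#' checksums byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest` (file -> md5).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: inputs
  if (!is.null(cfg$scenario)) {
    say("stage simulate: generating synthetic scenario")
    sim <- simulate_scenario(cfg$scenario, file.path(cfg$outdir, "data"),
                             k = cfg$k, min_mirnas = cfg$min_mirnas,
                             min_genes = cfg$min_genes,
                             evidence_filter = cfg$evidence_filter)
    mirna_expr <- sim$cohort$mirna_expr
    gene_expr <- sim$cohort$gene_expr
    clinical <- sim$cohort$clinical
    subpathways <- sim$subpathways
    planted <- sim$planted
  } else {
    say("stage load: reading inputs")
    mirna_expr <- read_expression_tsv(cfg$inputs$mirna_expr)
    gene_expr <- read_expression_tsv(cfg$inputs$gene_expr)
    clinical <- read_clinical_tsv(cfg$inputs$clinical)
    if (!is.null(cfg$inputs$subpathways)) {
      subpathways <- read_subpathways_json(cfg$inputs$subpathways)
    } else {
      kgml <- list.files(cfg$inputs$kgml_dir, pattern = "\\.xml$",
                         full.names = TRUE)
      pathways <- lapply(sort(kgml), parse_kgml)
      interactions <- read_interactions_tsv(cfg$inputs$interactions)
      subpathways <- build_subpathways(
        pathways, interactions, k = cfg$k, min_mirnas = cfg$min_mirnas,
        min_genes = cfg$min_genes, evidence_filter = cfg$evidence_filter)
      write_subpathways_json(subpathways,
                             file.path(cfg$outdir, "subpathways.json"))
    }
    planted <- character()
    sim <- NULL
  }
  say(sprintf("  %d subpathways, %d miRNAs x %d genes x %d samples",
              length(subpathways), nrow(mirna_expr), nrow(gene_expr),
              ncol(gene_expr)))

  # stage 2: cohort filtering and splits
  clinical <- suppressMessages(
    exclude_short_survivors(clinical, cfg$min_months))
  strata <- median_survival_strata(clinical)
  split <- stratified_split(clinical, cfg$train_frac,
                            seed = pipeline_seed(cfg, 11))
  subsets <- make_training_subsets(split$train, strata,
                                   n_subsets = cfg$n_subsets,
                                   frac = cfg$subset_frac,
                                   seed = pipeline_seed(cfg, 12))
  clin_train <- clinical[clinical$sample_id %in% split$train, , drop = FALSE]
  clin_test <- clinical[clinical$sample_id %in% split$test, , drop = FALSE]
  say(sprintf("stage split: %d train / %d test samples, %d subsets",
              nrow(clin_train), nrow(clin_test), length(subsets)))

  # stage 3: resampled screens and robustness ranking
  say("stage rank-robust: resampled Cox screens + subpathway calls")
  lists <- run_resampled_screens(
    subsets, mirna_expr, gene_expr, clin_train, subpathways,
    alpha_feature = cfg$alpha_feature,
    alpha_subpathway = cfg$alpha_subpathway,
    transform = cfg$transform,
    cache_dir = file.path(cfg$outdir, "cache"))
  robustness <- count_subpathway_hits(lists)
  utils::write.table(robustness,
                     file.path(cfg$outdir, "robustness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  selected <- select_robust(robustness, mode = cfg$selection$mode,
                            value = cfg$selection$value)
  say(sprintf("  top count %d; %d subpathway(s) selected",
              if (nrow(robustness)) max(robustness$count) else 0L,
              length(selected)))

  # stage 4: risk models and evaluation
  sub_by_id <- stats::setNames(subpathways, vapply(subpathways, `[[`,
                                                   character(1L),
                                                   "subpathway_id"))
  models <- lapply(sub_by_id[selected], fit_risk_model,
                   mirna_expr = mirna_expr, gene_expr = gene_expr,
                   clin_train = clin_train, transform = cfg$transform)
  if (length(models) >= 2L) {
    models$combined <- combined_fit(unname(models), mirna_expr, gene_expr,
                                    clin_train)
  }
  evaluations <- lapply(models, function(m) {
    list(train = evaluate_risk_model(m, mirna_expr, gene_expr, clin_train),
         test = evaluate_risk_model(m, mirna_expr, gene_expr, clin_test))
  })
  summary <- do.call(rbind, lapply(names(evaluations), function(nm) {
    ev <- evaluations[[nm]]
    data.frame(model = nm,
               cohort = c("train", "test"),
               logrank_chi2 = c(ev$train$logrank$chi2, ev$test$logrank$chi2),
               logrank_p = c(ev$train$logrank$p, ev$test$logrank$p),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(model = character(), cohort = character(),
                          logrank_chi2 = numeric(), logrank_p = numeric())
  }
  utils::write.table(format_num_df(summary),
                     file.path(cfg$outdir, "evaluation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(models)) {
    write_risk_models_json(models, file.path(cfg$outdir, "risk_models.json"))
    scores <- do.call(rbind, lapply(names(evaluations), function(nm) {
      ev <- evaluations[[nm]]
      do.call(rbind, lapply(c("train", "test"), function(coh) {
        data.frame(model = nm, cohort = coh,
                   sample_id = names(ev[[coh]]$scores),
                   score = unname(ev[[coh]]$scores),
                   group = unname(ev[[coh]]$groups[names(ev[[coh]]$scores)]),
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.table(format_num_df(scores),
                       file.path(cfg$outdir, "sample_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(set = c(rep("train", length(split$train)),
                       rep("test", length(split$test))),
               sample_id = c(split$train, split$test)),
    file.path(cfg$outdir, "split.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # manifest over every written artifact
  files <- sort(list.files(cfg$outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  manifest <- stats::setNames(as.list(unname(sums)), files)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say(sprintf("pipeline finished in %.1fs, %d files in manifest",
              as.numeric(difftime(Sys.time(), t_start, units = "secs")),
              length(files)))

  invisible(list(config = cfg, simulation = sim, planted = planted,
                 subpathways = subpathways, clinical = clinical,
                 split = split, subsets = subsets,
                 subset_calls = lists, robustness = robustness,
                 selected = selected, models = models,
                 evaluations = evaluations, summary = summary,
                 manifest = manifest))
}

pipeline_seed <- function(cfg, offset) {
  as.integer((as.double(cfg$seed) + offset) %% (.Machine$integer.max - 1))
}

# Fixed-format numeric columns so written tables are platform-stable.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  df
}
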