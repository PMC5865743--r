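#!/usr/bin/env Rscript
# Stage 5: risk scores and survival evaluation.  The most robust
# subpathways (top three dense ranks) each get a risk-score model — every
# measured member weighted by its training-set Cox coefficient — plus a
# combined model over the selected subpathways.  Cohorts are split at the
# training median score and the high/low groups compared with Kaplan-Meier
# curves and the log-rank test; the testing set is never used for fitting.
source("analysis/_common.R")

mirna_expr <- read_expression_tsv(file.path(DATA_DIR, "mirna_expression.tsv"))
gene_expr <- read_expression_tsv(file.path(DATA_DIR, "gene_expression.tsv"))
clinical <- read_clinical_tsv(file.path(DATA_DIR, "clinical.tsv"))
subs <- read_subpathways_json(file.path(DATA_DIR, "subpathways.json"))
split_tbl <- utils::read.delim(file.path(RESULTS_DIR, "split.tsv"))
tab <- utils::read.delim(file.path(RESULTS_DIR, "robustness.tsv"))

clinical <- exclude_short_survivors(clinical, min_months = 1)
clin_train <- clinical[clinical$sample_id %in%
                         split_tbl$sample_id[split_tbl$set == "train"], ]
clin_test <- clinical[clinical$sample_id %in%
                        split_tbl$sample_id[split_tbl$set == "test"], ]

selected <- select_robust(tab, mode = "top_n", value = 3)
message("selected robust subpathways: ", paste(selected, collapse = ", "))

sub_by_id <- setNames(subs, vapply(subs, `[[`, character(1), "subpathway_id"))
models <- lapply(sub_by_id[selected], fit_risk_model,
                 mirna_expr = mirna_expr, gene_expr = gene_expr,
                 clin_train = clin_train)
if (length(models) >= 2) {
  models$combined <- combined_fit(unname(models), mirna_expr, gene_expr,
                                  clin_train)
}
write_risk_models_json(models, file.path(RESULTS_DIR, "risk_models.json"))

rows <- list()
for (nm in names(models)) {
  for (cohort in c("train", "test")) {
    clin_c <- if (cohort == "train") clin_train else clin_test
    ev <- evaluate_risk_model(models[[nm]], mirna_expr, gene_expr, clin_c)
    rows[[length(rows) + 1]] <- data.frame(
      model = nm, cohort = cohort,
      n_high = sum(ev$groups == "high"), n_low = sum(ev$groups == "low"),
      logrank_chi2 = ev$logrank$chi2, logrank_p = ev$logrank$p)
    message(sprintf("  %-10s %-5s  chi2 %7.2f   log-rank P %.3g",
                    nm, cohort, ev$logrank$chi2, ev$logrank$p))
  }
}
write_tsv(do.call(rbind, rows), "evaluation_summary.tsv")
message("models with held-out log-rank P < 0.05: ",
        sum(vapply(rows, function(r) r$cohort == "test" && r$logrank_p < 0.05,
                   logical(1))), " of ", length(models))
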