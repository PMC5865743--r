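#!/usr/bin/env Rscript
# Stage 4: robustness ranking.  100 stratified half-subsets of the training
# set are drawn; in each one the Cox screen is repeated and every subpathway
# is tested with the pooled gene+miRNA hypergeometric statistic.  A
# subpathway's count — the number of subsets in which it is significant at
# P < 0.05 — measures how robustly it tracks survival.
source("analysis/_common.R")

mirna_expr <- read_expression_tsv(file.path(DATA_DIR, "mirna_expression.tsv"))
gene_expr <- read_expression_tsv(file.path(DATA_DIR, "gene_expression.tsv"))
clinical <- read_clinical_tsv(file.path(DATA_DIR, "clinical.tsv"))
subs <- read_subpathways_json(file.path(DATA_DIR, "subpathways.json"))
split_tbl <- utils::read.delim(file.path(RESULTS_DIR, "split.tsv"))
planted <- unlist(jsonlite::read_json(file.path(DATA_DIR, "planted.json")))

clinical <- exclude_short_survivors(clinical, min_months = 1)
train_ids <- intersect(split_tbl$sample_id[split_tbl$set == "train"],
                       clinical$sample_id)
clin_train <- clinical[clinical$sample_id %in% train_ids, ]
strata <- median_survival_strata(clinical)
subsets <- make_training_subsets(train_ids, strata[train_ids],
                                 n_subsets = N_SUBSETS, frac = 0.5,
                                 seed = MASTER_SEED + 12L)

message(sprintf("screening %d subsets of %d samples each ...",
                length(subsets), length(subsets[[1]])))
lists <- run_resampled_screens(subsets, mirna_expr, gene_expr, clin_train,
                               subs, cache_dir = file.path(RESULTS_DIR, "cache"))
tab <- count_subpathway_hits(lists)
write_tsv(tab, "robustness.tsv")

message("top 5 subpathways by robustness count:")
top <- utils::head(tab, 5)
for (i in seq_len(nrow(top))) {
  message(sprintf("  %-10s count %3d  mean p %.3g%s", top$subpathway_id[i],
                  top$count[i], top$mean_p[i],
                  if (top$subpathway_id[i] %in% planted) "  [planted]" else ""))
}
message(sprintf("planted subpathways hold ranks: %s",
                paste(tab$rank[tab$subpathway_id %in% planted], collapse = ", ")))
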