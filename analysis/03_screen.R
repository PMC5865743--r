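#!/usr/bin/env Rscript
# Stage 3: cohort hygiene and the full-training-set Cox screen.  Samples
# with under one month of follow-up are excluded, the cohort is split into
# stratified training and testing sets (preserving the good/poor survival
# ratio at the median), and every miRNA and gene is screened with a
# univariate Cox model on standardized log2(FPKM + 1) values.
source("analysis/_common.R")

mirna_expr <- read_expression_tsv(file.path(DATA_DIR, "mirna_expression.tsv"))
gene_expr <- read_expression_tsv(file.path(DATA_DIR, "gene_expression.tsv"))
clinical <- read_clinical_tsv(file.path(DATA_DIR, "clinical.tsv"))

clinical <- exclude_short_survivors(clinical, min_months = 1)
split <- stratified_split(clinical, train_frac = TRAIN_FRAC,
                          seed = MASTER_SEED + 11L)
write_tsv(data.frame(set = rep(c("train", "test"),
                               c(length(split$train), length(split$test))),
                     sample_id = c(split$train, split$test)),
          "split.tsv")
clin_train <- clinical[clinical$sample_id %in% split$train, ]
message(sprintf("%d training / %d testing samples",
                length(split$train), length(split$test)))

scr <- screen_features(mirna_expr, gene_expr, clin_train, alpha = 0.05)
write_tsv(scr$results[order(scr$results$p_value), ], "cox_screen_training.tsv")
message(sprintf("full training set: %d survival genes and %d survival miRNAs at P < 0.05 (of %d + %d measured)",
                length(scr$survival_genes), length(scr$survival_mirnas),
                scr$universe[["m_g"]], scr$universe[["m_mir"]]))
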