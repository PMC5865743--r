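# Shared settings for the numbered analysis scripts.  Every script can be
# run from the repository root with:  Rscript analysis/<script>.R
suppressMessages(library(miRSubSurv))

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
MASTER_SEED <- 42L

# Study conditions: 250 simulated patients (about 15% of whom die inside
# the first month and are excluded, as in a real AML cohort), 40 pathways
# with 3 carrying planted survival signal at a moderate log hazard ratio of
# 0.5 per member feature, and 100 stratified half-subsets for the
# robustness stage.  After exclusion the stratified split leaves roughly
# 150 training and 60 testing samples.
study_scenario <- function(seed = MASTER_SEED) {
  scenario_config(n_pathways = 40, genes_per_pathway = 8, edge_prob = 0.6,
                  n_mirnas = 60, interaction_prob = 0.012, n_samples = 250,
                  planted_subpathway_count = 3, effect_size_beta = 0.5,
                  censor_rate = 0.3, seed = seed)
}
TRAIN_FRAC <- 0.71
N_SUBSETS <- 100

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  path
}
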