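#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — pathway graphs, curated miRNA-gene
# interactions, and a right-censored expression cohort in which three
# subpathways carry planted prognostic signal.  All downstream stages read
# the files written here, so the whole analysis exercises the real I/O path.
source("analysis/_common.R")

cfg <- study_scenario()
sim <- simulate_scenario(cfg, DATA_DIR)

message(sprintf("simulated %d pathways, %d low-throughput interactions (of %d)",
                length(sim$pathways),
                sum(sim$interactions$evidence == "low-throughput"),
                nrow(sim$interactions)))
message(sprintf("%d miRNA-embedded subpathways pass the size filter (>=1 miRNA, >=3 genes)",
                length(sim$subpathways)))
message("planted prognostic subpathways: ", paste(sim$planted, collapse = ", "))
message(sprintf("cohort: %d samples, %.0f%% censored, median follow-up %.1f months",
                nrow(sim$cohort$clinical),
                100 * mean(sim$cohort$clinical$event == 0),
                median(sim$cohort$clinical$time_months)))
message("data written under ", DATA_DIR)
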