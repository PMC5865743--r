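#!/usr/bin/env Rscript
# Stage 2: characterise the reconstructed miRNA-embedded subpathways.
# Regions are maximal gene sets with pairwise pathway distance <= 3,
# miRNAs join a region when a low-throughput-verified interaction links
# them to at least one member gene, and regions with < 1 miRNA or < 3
# genes were dropped at construction.
source("analysis/_common.R")

subs <- read_subpathways_json(file.path(DATA_DIR, "subpathways.json"))

summary_tbl <- data.frame(
  subpathway_id = vapply(subs, `[[`, character(1), "subpathway_id"),
  parent_pathway = vapply(subs, `[[`, character(1), "parent_pathway"),
  n_genes = vapply(subs, function(s) length(s$genes), integer(1)),
  n_mirnas = vapply(subs, function(s) length(s$mirnas), integer(1)),
  n_gene_edges = vapply(subs, function(s) nrow(s$gene_edges), integer(1)),
  n_mirna_edges = vapply(subs, function(s) nrow(s$mirna_gene_edges), integer(1))
)
write_tsv(summary_tbl, "subpathway_summary.tsv")

message(sprintf("%d subpathways from %d pathways", nrow(summary_tbl),
                length(unique(summary_tbl$parent_pathway))))
message(sprintf("mean %.1f genes, %.1f miRNAs, %.1f miRNA-gene edges per subpathway",
                mean(summary_tbl$n_genes), mean(summary_tbl$n_mirnas),
                mean(summary_tbl$n_mirna_edges)))

# GraphML export of the largest region for external visualisation
big <- subs[[which.max(summary_tbl$n_genes + summary_tbl$n_mirnas)]]
dir.create(RESULTS_DIR, showWarnings = FALSE)
write_subpathway_graphml(big, file.path(RESULTS_DIR, "largest_subpathway.graphml"))
message("largest region ", big$subpathway_id, " exported as GraphML")
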