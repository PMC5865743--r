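test_that("scenario_config validates probabilities, counts and hazards", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(edge_prob = 1.2), "probability")
  expect_error(scenario_config(n_samples = 0), ">= 1")
  expect_error(scenario_config(baseline_hazard = 0), "> 0")
  expect_error(scenario_config(genes_per_pathway = 2), "size filter")
})

test_that("complete-graph limit yields one triangle pathway", {
  cfg <- scenario_config(n_pathways = 1, genes_per_pathway = 3,
                         edge_prob = 1, seed = 5)
  g <- generate_pathways(cfg)[[1]]
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 3)
})

test_that("edge_prob = 0 with bridging yields a connected tree", {
  cfg <- scenario_config(n_pathways = 3, genes_per_pathway = 10,
                         edge_prob = 0, seed = 2)
  for (g in generate_pathways(cfg)) {
    expect_equal(nrow(g$edges), length(g$nodes) - 1)
    expect_equal(igraph::components(miRSubSurv:::pathway_igraph(g))$no, 1)
  }
})

test_that("generated pathways are always connected with unique gene ids", {
  cfg <- scenario_config(n_pathways = 6, genes_per_pathway = 7,
                         edge_prob = 0.15, seed = 11)
  gs <- generate_pathways(cfg)
  all_genes <- unlist(lapply(gs, `[[`, "nodes"))
  expect_false(anyDuplicated(all_genes) > 0)
  for (g in gs) {
    expect_equal(igraph::components(miRSubSurv:::pathway_igraph(g))$no, 1)
  }
})

test_that("generators are deterministic under the master seed", {
  cfg <- scenario_config(n_pathways = 4, genes_per_pathway = 6,
                         edge_prob = 0.4, n_samples = 30, seed = 42)
  p1 <- generate_pathways(cfg); p2 <- generate_pathways(cfg)
  expect_identical(p1, p2)
  i1 <- generate_interactions(p1, cfg); i2 <- generate_interactions(p2, cfg)
  expect_identical(i1, i2)
  subs <- build_subpathways(p1, i1)
  if (length(subs)) {
    c1 <- generate_cohort(subs, character(), cfg, pathways = p1)
    c2 <- generate_cohort(subs, character(), cfg, pathways = p1)
    expect_identical(c1, c2)
  }
})

test_that("interaction table hits its saturated and empty limits", {
  cfg1 <- scenario_config(n_pathways = 2, genes_per_pathway = 4,
                          n_mirnas = 5, interaction_prob = 1, seed = 3)
  ps <- generate_pathways(cfg1)
  tbl <- generate_interactions(ps, cfg1)
  expect_equal(nrow(tbl), 5 * 8)
  cfg0 <- scenario_config(n_pathways = 2, genes_per_pathway = 4,
                          n_mirnas = 5, interaction_prob = 0, seed = 3)
  expect_equal(nrow(generate_interactions(ps, cfg0)), 0)
})

test_that("interaction row count matches an independent re-simulation", {
  cfg <- scenario_config(n_pathways = 1, genes_per_pathway = 5,
                         n_mirnas = 2, interaction_prob = 0.5, seed = 9)
  ps <- generate_pathways(cfg)
  tbl <- generate_interactions(ps, cfg)
  # re-draw the same Bernoulli stream directly
  set.seed(miRSubSurv:::substream_seed(cfg, 2))
  keep <- runif(2 * 5) < 0.5
  expect_equal(nrow(tbl), sum(keep))
})

make_scenario_subs <- function(cfg) {
  ps <- generate_pathways(cfg)
  tbl <- generate_interactions(ps, cfg)
  list(pathways = ps, subs = build_subpathways(ps, tbl))
}

test_that("cohort respects censoring and positivity contracts", {
  cfg <- scenario_config(n_pathways = 4, genes_per_pathway = 6,
                         n_mirnas = 15, interaction_prob = 0.08,
                         n_samples = 80, censor_rate = 0, seed = 21)
  sc <- make_scenario_subs(cfg)
  co <- generate_cohort(sc$subs, character(), cfg, pathways = sc$pathways)
  expect_true(all(co$clinical$event == 1))
  expect_true(all(co$gene_expr >= 0) && all(co$mirna_expr >= 0))
  expect_false(anyNA(co$gene_expr) || anyNA(co$mirna_expr))
  expect_error(generate_cohort(sc$subs, "nonexistent_id", cfg),
               "planted ids")
})

test_that("expected censor fraction tracks censor_rate", {
  cfg <- scenario_config(n_pathways = 4, genes_per_pathway = 6,
                         n_mirnas = 15, interaction_prob = 0.08,
                         n_samples = 2000, censor_rate = 0.4,
                         effect_size_beta = 0, seed = 33)
  sc <- make_scenario_subs(cfg)
  co <- generate_cohort(sc$subs, character(), cfg, pathways = sc$pathways)
  expect_lt(abs(mean(co$clinical$event == 0) - 0.4), 0.05)
})

test_that("null-scenario screening p-values are approximately uniform", {
  cfg <- scenario_config(n_pathways = 25, genes_per_pathway = 8,
                         n_mirnas = 50, interaction_prob = 0.02,
                         n_samples = 220, effect_size_beta = 0, seed = 14)
  sc <- make_scenario_subs(cfg)
  co <- generate_cohort(sc$subs, character(), cfg, pathways = sc$pathways)
  scr <- screen_features(co$mirna_expr, co$gene_expr, co$clinical)
  p <- scr$results$p_value[scr$results$status == "ok"]
  expect_gt(length(p), 200)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("fitted Cox coefficient on planted features matches a grid-search oracle", {
  cfg <- scenario_config(n_pathways = 6, genes_per_pathway = 6,
                         n_mirnas = 20, interaction_prob = 0.05,
                         n_samples = 300, effect_size_beta = 1,
                         planted_subpathway_count = 1, seed = 8)
  sc <- make_scenario_subs(cfg)
  expect_gt(length(sc$subs), 0)
  planted <- sc$subs[[1]]$subpathway_id
  co <- generate_cohort(sc$subs, planted, cfg, pathways = sc$pathways)
  feats <- intersect(co$planted_features, rownames(co$gene_expr))[1:3]
  for (f in feats) {
    x <- co$gene_expr[f, ]
    fit <- cox_univariate(x, co$clinical, feature_id = f)
    xl <- log2(x + 1); xs <- (xl - mean(xl)) / sd(xl)
    bhat <- oracle_cox_partial_likelihood(
      xs[co$clinical$sample_id], co$clinical$time_months, co$clinical$event)
    expect_equal(fit$coefficient, bhat, tolerance = 1e-3)
  }
})
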