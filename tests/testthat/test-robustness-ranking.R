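# small deterministic cohort + subpathways used across this file
make_toy_pipeline_inputs <- function(seed = 91) {
  cfg <- scenario_config(n_pathways = 6, genes_per_pathway = 6,
                         n_mirnas = 15, interaction_prob = 0.06,
                         n_samples = 60, effect_size_beta = 0, seed = seed)
  ps <- generate_pathways(cfg)
  tbl <- generate_interactions(ps, cfg)
  subs <- build_subpathways(ps, tbl)
  co <- generate_cohort(subs, character(), cfg, pathways = ps)
  list(cfg = cfg, subs = subs, co = co)
}

test_that("a single subset reproduces the manually composed stages", {
  ti <- make_toy_pipeline_inputs()
  ids <- ti$co$clinical$sample_id[1:30]
  lists <- run_resampled_screens(list(ids), ti$co$mirna_expr,
                                 ti$co$gene_expr, ti$co$clinical, ti$subs)
  expect_length(lists, 1)
  clin_b <- ti$co$clinical[ti$co$clinical$sample_id %in% ids, ]
  scr <- screen_features(ti$co$mirna_expr[, ids], ti$co$gene_expr[, ids],
                         clin_b)
  manual <- identify_survival_subpathways(
    ti$subs, scr$survival_genes, scr$survival_mirnas, scr$universe,
    rownames(ti$co$gene_expr), rownames(ti$co$mirna_expr))
  expect_equal(lists[[1]], manual)
})

test_that("alpha = 0 empties every per-subset list", {
  ti <- make_toy_pipeline_inputs()
  ids <- list(ti$co$clinical$sample_id[1:30], ti$co$clinical$sample_id[21:50])
  lists <- run_resampled_screens(ids, ti$co$mirna_expr, ti$co$gene_expr,
                                 ti$co$clinical, ti$subs,
                                 alpha_subpathway = 0)
  for (l in lists) expect_false(any(l$significant))
})

test_that("per-subset caching round-trips and enables resumption", {
  ti <- make_toy_pipeline_inputs()
  ids <- list(ti$co$clinical$sample_id[1:30])
  cache <- withr::local_tempdir()
  first <- run_resampled_screens(ids, ti$co$mirna_expr, ti$co$gene_expr,
                                 ti$co$clinical, ti$subs, cache_dir = cache)
  expect_true(file.exists(file.path(cache, "subset_0001.tsv")))
  again <- run_resampled_screens(ids, ti$co$mirna_expr, ti$co$gene_expr,
                                 ti$co$clinical, ti$subs, cache_dir = cache)
  expect_equal(first[[1]]$subpathway_id, again[[1]]$subpathway_id)
  expect_equal(first[[1]]$p_value, again[[1]]$p_value)
  expect_equal(first[[1]]$significant, again[[1]]$significant)
})

fake_lists <- function(flags_by_sub, p_by_sub) {
  # flags_by_sub: named list of logical vectors (one entry per subset)
  n <- length(flags_by_sub[[1]])
  lapply(seq_len(n), function(b) {
    data.frame(
      subpathway_id = names(flags_by_sub),
      p_value = vapply(p_by_sub, `[`, numeric(1), b),
      significant = vapply(flags_by_sub, `[`, logical(1), b),
      stringsAsFactors = FALSE
    )
  })
}

test_that("hit counting, mean p and dense ranks follow the tie rules", {
  set.seed(2)
  flags <- list(a = rep(c(TRUE, FALSE), c(48, 52)),
                b = rep(TRUE, 100),
                c = rep(c(TRUE, FALSE), c(48, 52)))
  ps <- list(a = c(runif(48, 0, 0.05), runif(52, 0.5, 1)),
             b = runif(100, 0, 0.01),
             c = c(runif(48, 0, 0.04) - 0.02, runif(52, 0.5, 1)))
  ps$c <- pmax(ps$c, 0)
  tab <- count_subpathway_hits(fake_lists(flags, ps))
  expect_equal(tab$count[tab$subpathway_id == "a"], 48L)
  expect_equal(tab$subpathway_id[tab$rank == 1], "b")
  expect_equal(tab$count[tab$subpathway_id == "b"], 100L)
  # a and c tie on count: dense rank equal, row order by mean_p then id
  expect_equal(tab$rank[tab$subpathway_id %in% c("a", "c")], c(2L, 2L))
  expect_lt(which(tab$subpathway_id == "c"), which(tab$subpathway_id == "a"))
})

test_that("selection honours dense-rank and min-count semantics", {
  tab <- data.frame(
    subpathway_id = c("s1", "s2", "s3", "s4", "s5"),
    count = c(48L, 47L, 47L, 44L, 40L),
    mean_p = c(0.01, 0.02, 0.03, 0.04, 0.05)
  )
  tab$rank <- match(tab$count, sort(unique(tab$count), decreasing = TRUE))
  expect_equal(select_robust(tab, "top_n", 3), c("s1", "s2", "s3", "s4"))
  expect_equal(select_robust(tab, "top_n", 1), "s1")
  expect_equal(select_robust(tab, "min_count", 47), c("s1", "s2", "s3"))
  expect_equal(select_robust(tab, "min_count", 101), character(0))
})

test_that("null scenarios never produce high robustness counts", {
  ti <- make_toy_pipeline_inputs(seed = 97)
  strata <- median_survival_strata(ti$co$clinical)
  subsets <- make_training_subsets(ti$co$clinical$sample_id, strata,
                                   n_subsets = 20, frac = 0.5, seed = 5)
  lists <- run_resampled_screens(subsets, ti$co$mirna_expr, ti$co$gene_expr,
                                 ti$co$clinical, ti$subs)
  tab <- count_subpathway_hits(lists)
  # with no signal, no subpathway should be significant in half the subsets
  expect_lt(max(tab$count), 10)
})

test_that("planted subpathways dominate counts in a strong-signal scenario", {
  cfg <- scenario_config(n_pathways = 10, genes_per_pathway = 7,
                         n_mirnas = 25, interaction_prob = 0.04,
                         n_samples = 160, effect_size_beta = 1.2,
                         seed = 3)
  ps <- generate_pathways(cfg)
  tbl <- generate_interactions(ps, cfg)
  subs <- build_subpathways(ps, tbl)
  ids <- vapply(subs, `[[`, character(1), "subpathway_id")
  planted <- ids[1:2]
  co <- generate_cohort(subs, planted, cfg, pathways = ps)
  strata <- median_survival_strata(co$clinical)
  subsets <- make_training_subsets(co$clinical$sample_id, strata,
                                   n_subsets = 20, frac = 0.5, seed = 4)
  lists <- run_resampled_screens(subsets, co$mirna_expr, co$gene_expr,
                                 co$clinical, subs)
  tab <- count_subpathway_hits(lists)
  planted_counts <- tab$count[tab$subpathway_id %in% planted]
  other <- setdiff(tab$subpathway_id, ids[startsWith(ids, substr(planted[1], 1, 5)) |
                                          startsWith(ids, substr(planted[2], 1, 5))])
  other_counts <- tab$count[tab$subpathway_id %in% other]
  expect_gt(mean(planted_counts), mean(other_counts))
})
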