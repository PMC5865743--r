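# deterministic 3-component fixture: 3 genes + 1 miRNA over 8 samples
risk_fixture <- local({
  set.seed(64)
  n <- 8
  clin <- make_clinical(sample(seq(2, 60, by = 2), n), rep(1, n))
  ge <- matrix(rexp(3 * n, 0.1), nrow = 3,
               dimnames = list(c("gA", "gB", "gC"), clin$sample_id))
  me <- matrix(rexp(1 * n, 0.1), nrow = 1,
               dimnames = list("m1", clin$sample_id))
  sub <- subpathway_graph("fix_1", "fix", genes = c("gA", "gB", "gC"),
                          mirna_gene_edges = cbind("m1", "gA"))
  list(clin = clin, ge = ge, me = me, sub = sub)
})

test_that("risk weights are the training-set univariate Cox coefficients", {
  fx <- risk_fixture
  model <- fit_risk_model(fx$sub, fx$me, fx$ge, fx$clin)
  expect_s3_class(model, "risk_score_model")
  expect_equal(model$components$feature_id, c("gA", "gB", "gC", "m1"))
  for (i in 1:3) {
    ref <- cox_univariate(fx$ge[model$components$feature_id[i], ], fx$clin)
    expect_equal(model$components$weight[i], ref$coefficient)
  }
  # score of a named sample equals the hand-computed linear combination
  s <- score_samples(model, fx$me, fx$ge)
  hand <- 0
  for (i in seq_len(nrow(model$components))) {
    cm <- model$components[i, ]
    x <- if (cm$kind == "gene") fx$ge[cm$feature_id, 3] else fx$me[cm$feature_id, 3]
    hand <- hand + cm$weight * (log2(x + 1) - cm$center) / cm$scale
  }
  expect_equal(unname(s[3]), hand)
  # training median is the median of training scores
  expect_equal(model$training_median, median(s))
})

test_that("degenerate components get weight zero; all-degenerate errors", {
  fx <- risk_fixture
  ge <- fx$ge; ge["gB", ] <- 5  # constant
  model <- fit_risk_model(fx$sub, fx$me, ge, fx$clin)
  expect_true(model$components$flagged[model$components$feature_id == "gB"])
  expect_equal(model$components$weight[model$components$feature_id == "gB"], 0)
  ge[] <- 1
  me <- fx$me; me[] <- 1
  expect_error(fit_risk_model(fx$sub, me, ge, fx$clin), "no usable components")
})

test_that("scores are linear with zero-weight and missing-feature guards", {
  fx <- risk_fixture
  model <- fit_risk_model(fx$sub, fx$me, fx$ge, fx$clin)
  zero <- model
  zero$components$weight[] <- 0
  expect_true(all(score_samples(zero, fx$me, fx$ge) == 0))
  # perturbing one covariate moves the score by weight * transformed delta
  ge2 <- fx$ge
  ge2["gA", 1] <- ge2["gA", 1] * 4
  d_x <- (log2(ge2["gA", 1] + 1) - log2(fx$ge["gA", 1] + 1)) /
    model$components$scale[1]
  d_s <- score_samples(model, fx$me, ge2)[1] - score_samples(model, fx$me, fx$ge)[1]
  expect_equal(unname(d_s), model$components$weight[1] * d_x)
  # a missing component feature is an error, not a silent drop
  expect_error(score_samples(model, fx$me, fx$ge[-1, , drop = FALSE]),
               "missing")
})

test_that("dichotomization sends ties to the low-risk group", {
  sc <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(unname(dichotomize(sc, 2.5)), c("low", "low", "high", "high"))
  expect_true(all(dichotomize(rep(2, 4), 2) == "low"))
  expect_equal(sum(dichotomize(c(1, 1, 5), 2) == "high"), 1)
})

test_that("combined models weight sub-scores by their training Cox fits", {
  fx <- risk_fixture
  m1 <- fit_risk_model(fx$sub, fx$me, fx$ge, fx$clin)
  expect_error(combined_fit(list(m1), fx$me, fx$ge, fx$clin), "at least 2")
  cmb <- combined_fit(list(m1, m1), fx$me, fx$ge, fx$clin)
  expect_equal(cmb$sub_weights[1], cmb$sub_weights[2])
  s1 <- score_samples(m1, fx$me, fx$ge)
  hand <- cmb$sub_weights[1] * s1[5] + cmb$sub_weights[2] * s1[5]
  expect_equal(unname(score_samples(cmb, fx$me, fx$ge)[5]), unname(hand))
})

test_that("Kaplan-Meier estimates follow the product-limit rules", {
  # no events: flat at 1
  clin0 <- make_clinical(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km_curve(clin0$sample_id, clin0)$surv == 1))
  # event, censor, event: S(1) = 2/3, S(3) = 0
  clin1 <- make_clinical(c(1, 2, 3), c(1, 0, 1))
  km <- km_curve(clin1$sample_id, clin1)
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  # all events at distinct times: S after k-th event = (n-k)/n
  clin2 <- make_clinical(c(3, 1, 7, 5), rep(1, 4))
  km2 <- km_curve(clin2$sample_id, clin2)
  expect_equal(km2$surv, c(3, 2, 1, 0) / 4)
  # monotone, bounded
  expect_true(all(diff(km2$surv) <= 0) && all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("log-rank matches the hand-computed fixture and its invariances", {
  clin <- make_clinical(c(1, 2, 2, 3), rep(1, 4), ids = c("a1", "a2", "b1", "b2"))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  lr <- logrank_test(groups, clin)
  expect_equal(lr$chi2, 25 / 17, tolerance = 1e-6)      # = 1.4706
  expect_equal(lr$chi2, oracle_logrank_chi2(clin$time_months, clin$event,
                                            unname(groups[clin$sample_id])),
               tolerance = 1e-12)
  expect_equal(lr$p, pchisq(25 / 17, 1, lower.tail = FALSE), tolerance = 1e-6)
  # label swap leaves chi2 unchanged
  swapped <- ifelse(groups == "A", "B", "A"); names(swapped) <- names(groups)
  expect_equal(logrank_test(swapped, clin)$chi2, lr$chi2)
  # identical event patterns give chi2 = 0, p = 1
  clin_eq <- make_clinical(c(1, 2, 1, 2), rep(1, 4),
                           ids = c("a1", "a2", "b1", "b2"))
  lr0 <- logrank_test(groups, clin_eq)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # one empty group is an error
  expect_error(logrank_test(c(a1 = "A", a2 = "A"), clin), "2 non-empty")
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(40)
  ps <- replicate(400, {
    n <- 40
    clin <- make_clinical(rexp(n, 0.05) + 1, rbinom(n, 1, 0.7),
                          ids = sprintf("P%02d", 1:n))
    g <- setNames(sample(rep(c("high", "low"), n / 2)), clin$sample_id)
    logrank_test(g, clin)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("evaluation dichotomizes at the training median without leakage", {
  set.seed(50)
  n <- 40
  clin <- make_clinical(runif(n, 1, 60), rbinom(n, 1, 0.8),
                        ids = sprintf("P%02d", 1:n))
  ge <- matrix(rexp(5 * n, 0.1), nrow = 5,
               dimnames = list(sprintf("g%d", 1:5), clin$sample_id))
  me <- matrix(rexp(2 * n, 0.1), nrow = 2,
               dimnames = list(c("m1", "m2"), clin$sample_id))
  sub <- subpathway_graph("e_1", "e", genes = sprintf("g%d", 1:3),
                          mirna_gene_edges = cbind("m1", "g1"))
  train <- clin[1:24, ]; test <- clin[25:40, ]
  model <- fit_risk_model(sub, me, ge, train)
  ev <- evaluate_risk_model(model, me, ge, test)
  expect_equal(ev$cutoff, model$training_median)
  expect_setequal(names(ev$scores), test$sample_id)
  expect_true(all(ev$groups[ev$scores > ev$cutoff] == "high"))
})
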