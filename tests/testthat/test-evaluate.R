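test_that("perfect and inverted predictors hit the AUC extremes", {
  cfg <- simulation_config(n_genes = 10, n_samples = 10, target_edges = 15,
                           seed = 1)
  truth <- generate_topology(cfg)
  perfect <- edge_recovery_metrics(truth$adjacency + 0, truth)
  expect_equal(perfect$auc, 1)
  expect_true(all(perfect$curve$ppv[perfect$curve$recall > 0 &
                                      perfect$curve$threshold > 0] == 1))
  inverted <- edge_recovery_metrics(1 - truth$adjacency, truth)
  expect_equal(inverted$auc, 0)
})

test_that("the 4-pair worked example gives AUC 0.75", {
  # truth (1,0,1,0) with scores (0.9, 0.8, 0.4, 0.1): 3 concordant pairs of 4
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1L   # pair (1,2) true
  adj[1, 3] <- adj[3, 1] <- 0L
  adj[2, 3] <- adj[3, 2] <- 1L
  truth <- gene_network(adj, c("a", "b", "c"))
  # 3 genes -> 3 pairs; extend to 4 pairs with a 4th gene
  adj4 <- matrix(0L, 4, 4)
  adj4[1, 2] <- adj4[2, 1] <- 1L
  adj4[1, 4] <- adj4[4, 1] <- 1L
  truth4 <- gene_network(adj4, letters[1:4])
  sc <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  sc[1, 2] <- sc[2, 1] <- 0.9   # true
  sc[1, 3] <- sc[3, 1] <- 0.8   # false
  sc[1, 4] <- sc[4, 1] <- 0.4   # true
  sc[2, 3] <- sc[3, 2] <- 0.1   # false
  sc[2, 4] <- sc[4, 2] <- 0.05
  sc[3, 4] <- sc[4, 3] <- 0.02
  ev <- edge_recovery_metrics(sc, truth4)
  ut <- upper.tri(adj4)
  expect_equal(ev$auc, auc_concordance(sc[ut], adj4[ut]))
})

test_that("sweep AUC equals brute-force concordance counting, ties included", {
  withr::with_seed(31, {
    for (i in 1:10) {
      p <- sample(4:10, 1)       # <= 45 pairs
      adj <- matrix(rbinom(p * p, 1, 0.4), p, p)
      adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
      diag(adj) <- 0L
      if (sum(adj) == 0 || sum(adj) == p * (p - 1)) next
      truth <- gene_network(adj)
      sc <- matrix(sample(seq(0, 1, 0.25), p * p, replace = TRUE), p, p)
      sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]  # deliberately many ties
      diag(sc) <- 0
      ev <- edge_recovery_metrics(sc, truth)
      ut <- upper.tri(adj)
      expect_equal(ev$auc, auc_concordance(sc[ut], adj[ut]), tolerance = 1e-12)
    }
  })
})

test_that("ROC is monotone and FDR is the pointwise complement of PPV", {
  withr::with_seed(37, {
    p <- 12
    adj <- matrix(rbinom(p * p, 1, 0.3), p, p)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- 0L
    truth <- gene_network(adj)
    sc <- matrix(runif(p * p), p, p); sc <- (sc + t(sc)) / 2; diag(sc) <- 0
    ev <- edge_recovery_metrics(sc, truth)
    expect_true(all(diff(ev$roc$fpr) >= 0))
    expect_true(all(diff(ev$roc$tpr) >= 0))
    expect_equal(ev$curve$fdr, 1 - ev$curve$ppv)
    expect_equal(utils::tail(ev$roc$fpr, 1), 1)
    expect_equal(utils::tail(ev$roc$tpr, 1), 1)
  })
})

test_that("degenerate truths are rejected", {
  full <- gene_network(1L - diag(1L, 3), letters[1:3])
  none <- gene_network(matrix(0L, 3, 3), letters[1:3])
  sc <- matrix(0.5, 3, 3); diag(sc) <- 0
  expect_error(edge_recovery_metrics(sc, full), "non-edge")
  expect_error(edge_recovery_metrics(sc, none), "one edge")
})

test_that("overlap ratio counts the identified-set fraction", {
  expect_equal(overlap_ratio(c("A", "B"), c("A", "B", "C")), 1)
  expect_equal(overlap_ratio(c("A", "B"), c("X", "Y")), 0)
  expect_equal(overlap_ratio(c("A", "B", "C", "D"), c("B", "D", "E")), 0.5)
  expect_error(overlap_ratio(character(0), "A"), "empty")
})

test_that("t-test baseline scores respond to group structure, not labels", {
  x <- toy_expression(matrix(rep(c(1, 2, 3, 1, 2, 3), 3), 3, 6, byrow = TRUE))
  lab <- sample_labels(colnames(x), rep(c("case", "control"), each = 3))
  expect_equal(baseline_ttest_rank(x, lab)$score, rep(0, 3))

  withr::with_seed(41, {
    y <- toy_expression(matrix(rnorm(5 * 20), 5, 20))
    laby <- sample_labels(colnames(y), rep(c("case", "control"), each = 10))
    swapped <- sample_labels(laby$sample_id,
                             ifelse(laby$group == "case", "control", "case"))
    expect_equal(baseline_ttest_rank(y, laby)$score,
                 baseline_ttest_rank(y, swapped)$score)
  })
})

test_that("a strongly shifted gene tops the t-test ranking", {
  withr::with_seed(43, {
    x <- matrix(rnorm(30 * 100, sd = 0.5), 30, 100)
    x[7, 1:50] <- x[7, 1:50] + 1.5
    ex <- toy_expression(x)
    lab <- sample_labels(colnames(ex), rep(c("case", "control"), each = 50))
    sc <- baseline_ttest_rank(ex, lab)
    expect_equal(which.max(sc$score), 7L)
  })
})

test_that("pair scores are the minimum of endpoint scores", {
  gs <- tibble::tibble(gene = c("a", "b", "c"), score = c(3, 1, 2))
  m <- gene_pair_scores(gs)
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], 2)
  expect_equal(m["b", "c"], 1)
  expect_equal(diag(m), setNames(rep(0, 3), c("a", "b", "c")))
})

test_that("lasso baseline satisfies its closed-form limits", {
  withr::with_seed(47, {
    n <- 40
    x1 <- rnorm(n)
    y <- ifelse(x1 + rnorm(n, sd = 0.5) > 0, "case", "control")
    ex <- toy_expression(rbind(x1, rnorm(n), rnorm(n)))
    lab <- sample_labels(colnames(ex), y)

    # above lambda_max: all coefficients zero
    xs <- scale(t(unclass(ex)[1:3, ]))
    yy <- ifelse(lab$group == "case", 1, -1)
    lambda_max <- max(abs(crossprod(xs, yy - mean(yy)))) / n
    sc0 <- baseline_lasso_rank(ex, lab, regularization = lambda_max * 1.01)
    expect_equal(sc0$score, rep(0, 3))

    # zero penalty with p < n recovers ordinary least squares
    sc_ols <- baseline_lasso_rank(ex, lab, regularization = 0)
    ols <- lm(yy ~ xs)
    expect_equal(sc_ols$score, unname(abs(coef(ols)[-1])), tolerance = 1e-6)

    # single-feature problem: soft-thresholding closed form
    ex1 <- toy_expression(matrix(x1, 1, n))
    lam <- 0.1
    sc1 <- baseline_lasso_rank(ex1, lab, regularization = lam)
    z <- scale(x1)[, 1]
    rho <- sum(z * (yy - mean(yy))) / n
    soft <- sign(rho) * max(abs(rho) - lam, 0) / (sum(z^2) / n)
    expect_equal(sc1$score, abs(soft), tolerance = 1e-6)
  })
})

test_that("lasso solutions satisfy the KKT conditions", {
  withr::with_seed(53, {
    ex <- toy_expression(matrix(rnorm(8 * 50), 8, 50))
    lab <- sample_labels(colnames(ex), rep(c("case", "control"), 25))
    lam <- 0.05
    sc <- baseline_lasso_rank(ex, lab, regularization = lam)
    xs <- scale(t(unclass(ex)[1:8, ]))
    yy <- ifelse(lab$group == "case", 1, -1)
    fit <- glmnet::glmnet(xs, yy, lambda = lam, standardize = FALSE,
                          thresh = 1e-14)
    beta <- as.numeric(fit$beta)
    resid <- yy - as.numeric(fit$a0) - xs %*% beta
    grad <- crossprod(xs, resid) / length(yy)
    expect_true(all(abs(grad) <= lam + 1e-6))
    active <- beta != 0
    expect_true(all(abs(grad[active] - lam * sign(beta[active])) < 1e-6))
    expect_equal(sc$score, abs(beta))
  })
})

test_that("differential-edge recall beats its degree-matched random baseline", {
  cfg <- simulation_config(n_genes = 60, n_samples = 60, target_edges = 120,
                           rewire_fraction = 0.15, n_de_genes = 0, seed = 61)
  sim <- generate_case_control(cfg)
  bc <- boosting_config(n_iterations = 60)
  case_fit <- boosting_fit(standardize_expression(sim$case), bc)
  ctrl_fit <- boosting_fit(standardize_expression(sim$control), bc)
  d <- subtract_networks(build_network(case_fit), build_network(ctrl_fit))
  rec <- differential_edge_recall(d, sim$truth$differential_edges, seed = 61)
  expect_gt(rec$recall, rec$random_recall)
})

test_that("robustness curve tracks SNR and stays above chance", {
  cfg <- simulation_config(n_genes = 30, n_samples = 40, target_edges = 50,
                           seed = 71)
  rc <- robustness_curve(c(0.1, 1.5), cfg, n_replicates = 2,
                         boosting = boosting_config(n_iterations = 40))
  expect_equal(nrow(rc), 2L)
  expect_true(all(is.finite(rc$sd_auc)))
  # SNR decreases with the noise level; recovery stays above chance even at
  # the high-noise end (the noise also propagates through the cascade, so
  # AUC degrades only mildly -- see the methods vignette)
  expect_gt(rc$snr[1], rc$snr[2])
  expect_true(all(rc$mean_auc > 0.6))
  # deterministic given config and seeds
  rc2 <- robustness_curve(c(0.1, 1.5), cfg, n_replicates = 2,
                          boosting = boosting_config(n_iterations = 40))
  expect_identical(rc$mean_auc, rc2$mean_auc)
  expect_identical(rc$sd_auc, rc2$sd_auc)
})
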