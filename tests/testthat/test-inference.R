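test_that("standardization centers and unit-norms rows", {
  x <- toy_expression(matrix(c(1, 2, 3), 1, 3))
  s <- standardize_expression(x)
  expect_equal(unname(unclass(s)[1, ]), c(-1, 0, 1) / sqrt(2))

  const <- toy_expression(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(s2 <- standardize_expression(const), "zero-variance")
  expect_equal(nrow(s2), 1L)
  expect_equal(rownames(s2), "g1")

  # idempotence up to floating tolerance
  expect_equal(unclass(standardize_expression(s))[1, ],
               unclass(s)[1, ], tolerance = 1e-12)
})

test_that("initial coefficients are pairwise correlations with zero diagonal", {
  v <- c(-1, 0, 1) / sqrt(2)
  x <- toy_expression(rbind(v, -v, c(0, 1, -1) - 0))
  x <- standardize_expression(x)
  beta <- initial_coefficients(x)
  expect_equal(diag(beta), setNames(rep(0, 3), rownames(x)))
  expect_equal(unname(beta[1, 2]), -1)             # opposite rows
  expect_equal(unname(beta[2, 1]), -1)
  expect_equal(beta, t(beta))

  # orthogonal and identical rows
  o <- orthonormal_rows(2, 6, seed = 3)
  xo <- expression_matrix(rbind(o, g_copy = o[1, ]), log_scale = TRUE)
  b2 <- initial_coefficients(xo)
  expect_equal(unname(b2[1, 2]), 0, tolerance = 1e-12)
  expect_equal(unname(b2[1, 3]), 1, tolerance = 1e-12)
})

test_that("residual sum of squares matches hand arithmetic", {
  o <- orthonormal_rows(2, 6, seed = 5)
  x <- expression_matrix(o, log_scale = TRUE)
  # zero coefficients on a unit-norm target
  expect_equal(residual_sum_squares(x, 1, c(0, 0)), 1)
  # perfect fit: x2 reproduced by itself is not allowed, use a copy gene
  x3 <- expression_matrix(rbind(o, g_copy = o[1, ]), log_scale = TRUE)
  expect_equal(residual_sum_squares(x3, 3, c(1, 0, 0)), 0, tolerance = 1e-20)
  # 2-gene, 2-sample unstandardized toy: x1 = (1,0), x2 = (0,1), beta12 = 0.5
  toy <- expression_matrix(rbind(c(1, 0), c(0, 1)), log_scale = TRUE)
  expect_equal(residual_sum_squares(toy, 1, c(0, 0.5)), 1.25)
  expect_error(residual_sum_squares(toy, 1, c(0.2, 0.5)), "zero at the target")
})

test_that("perfect power-law degree histogram gives the maximal prior", {
  # counts {8, 4, 2, 1} over bins {1, 2, 4, 8}: log-frequency exactly linear
  # in log-degree, so |C| = 1 and log(C^2) = 0
  degs <- rep(c(1, 2, 4, 8), c(8, 4, 2, 1))
  p <- length(degs)
  beta <- matrix(0, p, p)
  beta[1, 2:p] <- degs[2:p]
  beta[2, 1] <- degs[1]
  pr <- scale_free_prior(beta)
  expect_equal(pr$c, -1)
  expect_equal(pr$log_prior, 0)
})

test_that("degenerate degree histograms give the neutral prior", {
  beta <- matrix(0, 4, 4)
  beta[1, 2] <- 1; beta[1, 3] <- 2; beta[1, 4] <- 2  # bins {1, 2} only
  pr <- scale_free_prior(beta)
  expect_true(is.na(pr$c))
  expect_equal(pr$log_prior, 0)
})

test_that("three-bin prior matches the closed-form Pearson oracle", {
  # counts {5, 3, 2} over bins {1, 2, 3} (frequencies 0.5 / 0.3 / 0.2)
  degs <- rep(c(1, 2, 3), c(5, 3, 2))
  p <- length(degs)
  beta <- matrix(0, p, p)
  beta[1, 2:p] <- degs[2:p]
  beta[2, 1] <- degs[1]
  pr <- scale_free_prior(beta)
  lx <- log(c(1, 2, 3)); ly <- log(c(0.5, 0.3, 0.2))
  cc <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(pr$c, cc, tolerance = 1e-12)
  expect_equal(pr$log_prior, log(cc^2), tolerance = 1e-12)
})

test_that("posterior score evaluates and decomposes exactly", {
  expect_equal(posterior_score(1, 0, 1e-300), 0, tolerance = 1e-12)
  expect_equal(posterior_score(exp(-1), 0, 1e-300), 1, tolerance = 1e-12)
  eps <- 1e-12
  expect_equal(posterior_score(0.5, log(0.81), eps),
               -log(0.5 + eps) + log(0.81), tolerance = 1e-15)
  # decomposition: likelihood term + prior term, recomputed independently
  withr::with_seed(1, {
    for (i in 1:20) {
      rss <- runif(1); lp <- log(runif(1)^2)
      expect_equal(posterior_score(rss, lp, eps),
                   (-log(rss + eps)) + lp, tolerance = 1e-12)
    }
  })
})

test_that("zero boosting iterations give the zero matrix", {
  x <- expression_matrix(orthonormal_rows(3, 8, seed = 2), log_scale = TRUE)
  fit <- boosting_fit(x, boosting_config(n_iterations = 0))
  expect_true(all(fit$beta == 0))
})

test_that("boosting rejects non-standardized input", {
  x <- toy_expression(matrix(rnorm(30, mean = 5), 3, 10))
  expect_error(boosting_fit(x), "standardized")
})

test_that("the dominant predictor is selected first and noise genes never", {
  for (sd in 0:9) {
    withr::with_seed(sd, {
      n <- 20
      x1 <- rnorm(n); x2 <- rnorm(n)
      x3 <- 0.8 * x1
      xs <- standardize_expression(toy_expression(rbind(x1, x2, x3),
                                                  genes = c("g1", "g2", "g3")))
      # brute-force oracle: gene 1 has the largest |residual correlation|
      # with gene 3 at the start (they are identical after standardization)
      b0 <- initial_coefficients(xs)
      expect_gt(abs(b0["g3", "g1"]), abs(b0["g3", "g2"]))
      fit <- boosting_fit(xs, boosting_config(n_iterations = 50))
      g3 <- fit$trace[fit$trace$gene == "g3" & fit$trace$iteration > 0, ]
      expect_gt(nrow(g3), 0)
      expect_equal(unname(fit$beta["g3", "g2"]), 0)
      expect_gt(fit$beta["g3", "g1"], 0)
    })
  }
})

test_that("per-target score sequences are non-decreasing and recomputable", {
  cfg <- simulation_config(n_genes = 10, n_samples = 20, target_edges = 15,
                           seed = 4)
  net <- generate_topology(cfg)
  xs <- standardize_expression(generate_expression(net, cfg))
  conf <- boosting_config(n_iterations = 25)
  fit <- boosting_fit(xs, conf)
  for (g in unique(fit$trace$gene)) {
    sc <- fit$trace$score[fit$trace$gene == g]
    expect_true(all(diff(sc) > -1e-9))
  }
  # stored scores decompose as -log(rss + eps) + log_prior
  expect_equal(fit$trace$score,
               -log(fit$trace$rss + conf$rss_epsilon) + fit$trace$log_prior,
               tolerance = 1e-12)
  # final per-target rss matches an independent recomputation from beta;
  # coefficients below coefficient_zero_tol were zeroed, hence the tolerance
  ids <- fit$gene_ids
  for (i in seq_along(ids)) {
    rss_last <- tail(fit$trace$rss[fit$trace$gene == ids[i]], 1)
    expect_equal(residual_sum_squares(xs, i, fit$beta[i, ]), rss_last,
                 tolerance = 1e-8)
  }
})

test_that("prior-disabled boosting recovers projections on orthonormal designs", {
  o <- orthonormal_rows(4, 12, seed = 6)
  target <- 0.7 * o[1, ] + 0.4 * o[2, ] - 0.5 * o[3, ]
  target <- target - mean(target)
  target <- target / sqrt(sum(target^2))
  xs <- expression_matrix(rbind(o, tgt = target), log_scale = TRUE)
  fit <- boosting_fit(xs, boosting_config(n_iterations = 500),
                      use_prior = FALSE)
  proj <- as.vector(o %*% target)       # closed-form least squares
  expect_equal(unname(fit$beta["tgt", 1:4]), proj, tolerance = 1e-3)
})

test_that("boosting is deterministic given input and config", {
  cfg <- simulation_config(n_genes = 15, n_samples = 25, target_edges = 25,
                           seed = 9)
  xs <- standardize_expression(generate_expression(generate_topology(cfg), cfg))
  f1 <- boosting_fit(xs, boosting_config(n_iterations = 20))
  f2 <- boosting_fit(xs, boosting_config(n_iterations = 20))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$trace, f2$trace)
})

test_that("network binarization follows the coefficient sign rule", {
  beta <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  beta["a", "b"] <- 0.5; beta["b", "a"] <- -0.2   # product != 0 -> edge
  beta["a", "c"] <- 0.5                            # one-sided -> no edge
  net <- build_network(beta)
  expect_equal(unname(net$adjacency["a", "b"]), 1L)
  expect_equal(unname(net$adjacency["a", "c"]), 0L)
  strict <- build_network(beta, rule = "same_sign")
  expect_equal(unname(strict$adjacency["a", "b"]), 0L)
  expect_equal(n_edges(build_network(matrix(0, 4, 4))), 0L)
})

test_that("binarized networks are symmetric with zero diagonal", {
  withr::with_seed(21, {
    for (i in 1:10) {
      beta <- matrix(rnorm(36) * rbinom(36, 1, 0.4), 6, 6)
      diag(beta) <- 0
      net <- build_network(beta)
      expect_identical(net$adjacency, t(net$adjacency))
      expect_true(all(diag(net$adjacency) == 0L))
    }
  })
})

test_that("edge scores are the weaker absolute coefficient of a pair", {
  beta <- matrix(0, 2, 2)
  beta[1, 2] <- 0.5; beta[2, 1] <- -0.2
  sc <- edge_scores(beta)
  expect_equal(sc[1, 2], 0.2)
  expect_equal(sc, t(sc))
})
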