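#' Edge-recovery ROC/AUC/PPV/FDR
#'
#' Compares per-pair prediction scores against a ground-truth network.
#' Thresholds sweep the distinct score values from high to low; tied scores
#' are grouped into a single threshold step. AUC is the trapezoidal integral
#' of the ROC curve (equal to the Mann-Whitney concordance probability); the
#' PPV (precision) and FDR (= 1 - PPV) curves are reported against recall.
#'
#' @param scores Either a symmetric p x p score matrix (e.g. from
#'   [edge_scores()]), a [gene_network()] (binary scores), or a tibble with
#'   columns `gene_a`, `gene_b`, `score` covering every unordered pair of the
#'   truth's genes.
#' @param truth A [gene_network()] with at least one edge and one non-edge.
#' @return A list of class `edge_eval`: `auc`, `roc` (tibble `fpr`, `tpr`
#'   including the (0,0) and (1,1) anchors), `curve` (tibble `threshold`,
#'   `recall`, `ppv`, `fdr`), `n_pos`, `n_neg`.
#' @export
edge_recovery_metrics <- function(scores, truth) {
  stopifnot(inherits(truth, "gene_network"))
  ids <- truth$gene_ids
  ut <- upper.tri(truth$adjacency)
  y <- truth$adjacency[ut]

  if (inherits(scores, "gene_network")) {
    if (!identical(scores$gene_ids, ids))
      stop("score and truth networks must share the same gene universe",
           call. = FALSE)
    s <- scores$adjacency[ut] + 0
  } else if (is.matrix(scores)) {
    if (!all(dim(scores) == length(ids)))
      stop("score matrix dimension must match the gene universe", call. = FALSE)
    if (!is.null(rownames(scores)) && !identical(rownames(scores), ids))
      scores <- scores[ids, ids]
    s <- scores[ut]
  } else if (is.data.frame(scores)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    idx <- which(ut, arr.ind = TRUE)
    want <- key(ids[idx[, 1L]], ids[idx[, 2L]])
    have <- key(as.character(scores$gene_a), as.character(scores$gene_b))
    m <- match(want, have)
    if (anyNA(m)) stop("scores must cover every unordered gene pair", call. = FALSE)
    s <- as.numeric(scores$score[m])
  } else stop("unsupported scores input", call. = FALSE)

  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain at least one edge and one non-edge", call. = FALSE)

  ord <- order(-s)
  s_ord <- s[ord]
  y_ord <- y[ord]
  cum_tp <- cumsum(y_ord == 1L)
  cum_fp <- cumsum(y_ord == 0L)
  # last prediction of each tied-score block (one threshold step per block)
  last <- which(c(s_ord[-1L] != s_ord[-length(s_ord)], TRUE))
  thr <- s_ord[last]
  tp <- cum_tp[last]; fp <- cum_fp[last]
  tpr <- tp / n_pos; fpr <- fp / n_neg
  ppv <- tp / (tp + fp)

  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(
    auc = auc, roc = roc,
    curve = tibble::tibble(threshold = thr, recall = tpr, ppv = ppv,
                           fdr = 1 - ppv),
    n_pos = n_pos, n_neg = n_neg
  ), class = "edge_eval")
}

#' @export
print.edge_eval <- function(x, ...) {
  cat(sprintf("edge_eval: AUC = %.4f (%d true edges, %d non-edges)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname glance.edge_eval
#' @export
tidy.edge_eval <- function(x, ...) x$curve

#' Tidy and summarize an edge-recovery evaluation
#'
#' `tidy()` returns the threshold/recall/PPV/FDR curve; `glance()` a one-row
#' summary with the AUC.
#'
#' @param x An `edge_eval` from [edge_recovery_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.edge_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Overlap ratio with a reference gene set
#'
#' `|identified intersect reference| / |identified|` — the fraction of
#' identified genes that are corroborated by an external reference list.
#'
#' @param identified Non-empty character vector of identified genes.
#' @param reference Character vector (treated as a set) of reference genes.
#' @return A number in `[0, 1]`.
#' @export
overlap_ratio <- function(identified, reference) {
  identified <- unique(as.character(identified))
  if (!length(identified)) stop("identified gene list is empty", call. = FALSE)
  length(intersect(identified, reference)) / length(identified)
}

#' t-test baseline gene and pair scores
#'
#' Gene-based comparison baseline: each gene is scored by the absolute
#' two-sample t-statistic between case and control samples. For comparison on
#' the edge-recovery metric, per-pair scores are the minimum of the two
#' endpoint scores (a pair is as credible as its weaker gene); use
#' [gene_pair_scores()].
#'
#' @param expr A log2-scale [expression_matrix()].
#' @param labels A [sample_labels()] tibble.
#' @return A tibble with columns `gene`, `score` (= `|t|`).
#' @export
baseline_ttest_rank <- function(expr, labels) {
  de <- differential_expression(expr, labels)
  sc <- abs(de$t_statistic)
  sc[!is.finite(sc)] <- max(c(1, sc[is.finite(sc)])) * 2  # zero-variance separations
  tibble::tibble(gene = de$gene, score = sc)
}

#' Lasso baseline gene and pair scores
#'
#' Gene-based comparison baseline: an L1-penalized linear model of the
#' case/control label (coded +1/-1) on the gene expression values; genes are
#' scored by the absolute coefficient at the given regularization strength.
#' Backed by a coordinate-descent solver (glmnet) with a tight convergence
#' threshold so the lasso KKT conditions hold at the solution.
#'
#' @param expr A log2-scale [expression_matrix()].
#' @param labels A [sample_labels()] tibble.
#' @param regularization Lasso penalty `lambda`; the default `NULL` uses
#'   `0.1 * lambda_max` of the standardized problem, keeping a sparse but
#'   non-empty model.
#' @return A tibble with columns `gene`, `score` (= `|coefficient|`), plus
#'   the penalty used as attribute `"regularization"`.
#' @export
baseline_lasso_rank <- function(expr, labels, regularization = NULL) {
  grp <- check_labels(expr, labels, min_per_group = 1L)
  x <- t(unclass(expr)[seq_len(nrow(expr)), , drop = FALSE])
  y <- ifelse(grp == "case", 1, -1)
  # standardized features; glmnet's lambda_max is max |x_j' y| / n on them
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  if (is.null(regularization)) {
    lambda_max <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
    regularization <- 0.1 * lambda_max
  }
  p <- ncol(xs)
  if (p == 1L) xs <- cbind(xs, 0)  # the solver needs >= 2 columns; a zero
                                   # column never enters the model
  fit <- glmnet::glmnet(xs, y, family = "gaussian", lambda = regularization,
                        standardize = FALSE, thresh = 1e-14)
  beta <- as.numeric(fit$beta)[seq_len(p)]
  out <- tibble::tibble(gene = rownames(expr), score = abs(beta))
  attr(out, "regularization") <- regularization
  out
}

#' Map per-gene scores to per-pair scores
#'
#' `score(i, j) = min(score_i, score_j)`: a pair prediction from a gene-based
#' method is only as strong as its weaker endpoint.
#'
#' @param gene_scores Tibble with columns `gene`, `score` (e.g. from
#'   [baseline_ttest_rank()]).
#' @return A symmetric score matrix with zero diagonal.
#' @export
gene_pair_scores <- function(gene_scores) {
  s <- gene_scores$score
  m <- outer(s, s, pmin)
  diag(m) <- 0
  dimnames(m) <- list(gene_scores$gene, gene_scores$gene)
  m
}

#' Benchmark network inference against gene-based baselines
#'
#' For each replicate, generates a case/control benchmark with known ground
#' truth, infers a network from the control samples by posterior-score
#' boosting (the control arm is exactly the single-condition benchmark: base
#' topology, `n_samples` samples, noise `noise_sigma`), and evaluates
#' edge-recovery AUC against the base network. The t-test and lasso baselines
#' score genes from the full labeled case+control data and are mapped to
#' pairs by [gene_pair_scores()].
#'
#' @param config A [simulation_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param n_replicates Number of independent replicates (default 10).
#' @param boosting A [boosting_config()].
#' @param methods Subset of `c("netsam", "ttest", "lasso")`.
#' @return A tibble of class `netsam_benchmark` with columns `method`,
#'   `replicate`, `seed`, `auc`.
#' @export
benchmark_methods <- function(config = simulation_config(),
                              n_replicates = 10L,
                              boosting = boosting_config(),
                              methods = c("netsam", "ttest", "lasso")) {
  methods <- match.arg(methods, several.ok = TRUE)
  res <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- generate_case_control(cfg)
    truth <- sim$truth$control_network
    rows <- list()
    if ("netsam" %in% methods) {
      fit <- boosting_fit(standardize_expression(sim$control), boosting)
      ev <- edge_recovery_metrics(edge_scores(fit), truth)
      rows <- c(rows, list(tibble::tibble(method = "netsam", auc = ev$auc)))
    }
    if (any(c("ttest", "lasso") %in% methods)) {
      expr <- cbind_expression(sim$case, sim$control)
      if ("ttest" %in% methods) {
        sc <- gene_pair_scores(baseline_ttest_rank(expr, sim$labels))
        ev <- edge_recovery_metrics(sc, truth)
        rows <- c(rows, list(tibble::tibble(method = "ttest", auc = ev$auc)))
      }
      if ("lasso" %in% methods) {
        sc <- gene_pair_scores(baseline_lasso_rank(expr, sim$labels))
        ev <- edge_recovery_metrics(sc, truth)
        rows <- c(rows, list(tibble::tibble(method = "lasso", auc = ev$auc)))
      }
    }
    out <- dplyr::bind_rows(rows)
    out$replicate <- r
    out$seed <- cfg$seed
    out[, c("method", "replicate", "seed", "auc")]
  })
  class(res) <- c("netsam_benchmark", class(res))
  res
}

#' Robustness of edge recovery against noise
#'
#' Repeats the single-condition benchmark across noise levels: for each
#' `noise_sigma`, simulates `n_replicates` independent datasets, infers a
#' network by boosting, and records the edge-recovery AUC. SNR is reported as
#' the generative signal variance divided by `noise_sigma^2`, where the
#' signal variance is the mean per-gene variance attributable to parents.
#'
#' @param noise_sigmas Numeric vector of noise levels.
#' @param config Base [simulation_config()] (its `noise_sigma` is replaced).
#' @param n_replicates Replicates per noise level (>= 2).
#' @param boosting A [boosting_config()].
#' @return A tibble of class `netsam_robustness`: `noise_sigma`, `snr`,
#'   `mean_auc`, `sd_auc`, `n_replicates`.
#' @export
robustness_curve <- function(noise_sigmas, config = simulation_config(),
                             n_replicates = 5L,
                             boosting = boosting_config()) {
  stopifnot(n_replicates >= 2)
  res <- purrr::map_dfr(noise_sigmas, function(sg) {
    aucs <- signal <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$noise_sigma <- sg
      cfg$seed <- config$seed + (r - 1L)
      net <- generate_topology(cfg)
      x <- generate_expression(net, cfg)
      wm <- attr(x, "weights")
      xm <- unclass(x)[seq_len(nrow(x)), , drop = FALSE]
      # per-gene variance explained by parents, averaged over non-root genes
      child <- which(colSums(wm != 0) > 0)
      signal[r] <- if (length(child)) {
        mean(vapply(child, function(j) {
          pa <- which(wm[, j] != 0)
          stats::var(as.vector(crossprod(xm[pa, , drop = FALSE], wm[pa, j])))
        }, numeric(1)))
      } else 0
      fit <- boosting_fit(standardize_expression(x), boosting)
      aucs[r] <- edge_recovery_metrics(edge_scores(fit), net)$auc
    }
    tibble::tibble(noise_sigma = sg, snr = mean(signal) / sg^2,
                   mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                   n_replicates = n_replicates)
  })
  class(res) <- c("netsam_robustness", class(res))
  res
}

#' Recall of planted differential edges
#'
#' Fraction of true differential edges recovered in a predicted differential
#' network, together with the recall of a degree-matched random edge set (the
#' chance baseline): the predicted edges with gene labels randomly permuted,
#' which preserves the predicted degree sequence exactly while destroying any
#' association with the truth. The random recall is averaged over
#' `n_permutations` draws.
#'
#' @param predicted A [differential_network()].
#' @param truth_edges Tibble of true differential edges (`gene_a`, `gene_b`).
#' @param seed Seed for the permutation draws.
#' @param n_permutations Number of label permutations (default 20).
#' @return A one-row tibble: `recall`, `random_recall`, `n_true`,
#'   `n_predicted`.
#' @export
differential_edge_recall <- function(predicted, truth_edges, seed = 1L,
                                     n_permutations = 20L) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth_key <- key(truth_edges$gene_a, truth_edges$gene_b)
  pred_key <- key(predicted$edges$gene_a, predicted$edges$gene_b)
  recall <- mean(truth_key %in% pred_key)
  ids <- predicted$gene_ids
  random_recall <- withr::with_seed(seed, {
    mean(vapply(seq_len(n_permutations), function(i) {
      perm <- stats::setNames(sample(ids), ids)
      rnd_key <- key(perm[predicted$edges$gene_a],
                     perm[predicted$edges$gene_b])
      mean(truth_key %in% rnd_key)
    }, numeric(1)))
  })
  tibble::tibble(recall = recall, random_recall = random_recall,
                 n_true = length(truth_key), n_predicted = length(pred_key))
}
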