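#' Standardize expression rows
#'
#' Centers each gene's expression profile to mean 0 and scales it to unit
#' Euclidean norm, so that inner products between gene rows are Pearson
#' correlations. Zero-variance genes cannot be standardized and are dropped
#' with a warning.
#'
#' @param expr An [expression_matrix()].
#' @return An [expression_matrix()] whose rows have mean 0 and norm 1.
#' @export
standardize_expression <- function(expr) {
  x <- unclass(expr)[seq_len(nrow(expr)), , drop = FALSE]
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  keep <- nrm > 0
  if (!any(keep)) stop("all genes have zero variance", call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(x)[!keep], 5L), collapse = ", "),
            call. = FALSE)
  x <- x[keep, , drop = FALSE] / nrm[keep]
  expression_matrix(x, log_scale = is_log_scale(expr))
}

is_standardized <- function(x, tol = 1e-6) {
  all(abs(rowMeans(x)) < tol) && all(abs(rowSums(x^2) - 1) < tol)
}

#' Initial regression coefficients
#'
#' The starting coefficient matrix of the network-inference stage:
#' `beta[i, j] = x_j^T x_i` for `i != j`, the inner product of standardized
#' gene rows, i.e. the Pearson correlation of genes i and j; the diagonal
#' is zero. Row i holds the coefficients of the regression of gene i on all
#' other genes.
#'
#' @param expr A standardized [expression_matrix()]
#'   (see [standardize_expression()]).
#' @return A p x p numeric matrix with zero diagonal and gene IDs as dimnames.
#' @export
initial_coefficients <- function(expr) {
  x <- unclass(expr)[seq_len(nrow(expr)), , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (!is_standardized(x))
    stop("expression must be standardized (standardize_expression())",
         call. = FALSE)
  beta <- tcrossprod(x)
  diag(beta) <- 0
  beta
}

#' Residual sum of squares of one gene's regression
#'
#' `RSS_i = sum_k (x_ki - sum_j beta[i, j] x_kj)^2`, the squared error of
#' regressing gene i's profile on the linear combination of the other genes.
#'
#' @param expr An [expression_matrix()] (or plain genes x samples matrix).
#' @param target Row index of the target gene i.
#' @param beta_row Length-p coefficient vector with `beta_row[target] == 0`.
#' @return Nonnegative scalar.
#' @export
residual_sum_squares <- function(expr, target, beta_row) {
  x <- unclass(expr)
  if (length(beta_row) != nrow(x))
    stop("beta_row length must equal the number of genes", call. = FALSE)
  if (beta_row[target] != 0)
    stop("beta_row must be zero at the target gene (no self-regression)",
         call. = FALSE)
  resid <- x[target, ] - as.vector(crossprod(x, beta_row))
  sum(resid^2)
}

# Log-prior from an integer degree-bin histogram.
# h: counts indexed by bin (bin b occupied iff h[b] > 0).
prior_from_hist <- function(h) {
  occ <- which(h > 0)
  if (length(occ) < 3L) return(list(c = NA_real_, log_prior = 0))
  lx <- log(occ)
  ly <- log(h[occ])
  if (stats::sd(ly) == 0) return(list(c = NA_real_, log_prior = 0))
  cc <- stats::cor(lx, ly)
  list(c = cc, log_prior = log(cc^2))
}

degree_bins <- function(d) pmax(as.integer(round(d)), 1L)

#' Scale-free network prior score
#'
#' Measures how closely the weighted-degree distribution of a coefficient
#' matrix follows a power law `pi(d) ~ d^-lambda` (the scale-free property).
#' The weighted degree of gene j is `d_j = sum_m |beta[m, j]|`; degrees are
#' binned to positive integers (rounded, floored at 1); `pi(d)` is the
#' empirical relative frequency of each occupied bin; and
#' `C = cor(log pi(d), log d)` over occupied bins. A perfect power law makes
#' log-frequency exactly linear in log-degree, so `|C| = 1` and the log-prior
#' `log(C^2)` reaches its maximum 0. With fewer than 3 distinct occupied bins,
#' or when `C` is undefined, the prior is neutral (`log_prior = 0`,
#' `c = NA`).
#'
#' @param beta p x p coefficient matrix (see [initial_coefficients()]).
#' @param lambda Reference power-law exponent (> 0). The empirical-frequency
#'   formulation scores log-log linearity, so `lambda` does not enter the
#'   value of `C`; it documents the exponent the prior is anchored to.
#' @return A list with elements `c` (Pearson correlation, `NA` when
#'   degenerate), `log_prior` (`log(c^2)`, <= 0), and `degree` (named
#'   weighted-degree vector).
#' @export
scale_free_prior <- function(beta, lambda = 2.5) {
  stopifnot(lambda > 0)
  if (nrow(beta) < 2L) stop("need at least 2 genes", call. = FALSE)
  d <- colSums(abs(beta))
  bins <- degree_bins(d)
  h <- tabulate(bins, nbins = max(bins))
  pr <- prior_from_hist(h)
  list(c = pr$c, log_prior = pr$log_prior,
       degree = stats::setNames(d, colnames(beta)))
}

#' Posterior network score
#'
#' The structure-selection objective: `-log(RSS + epsilon) + log_prior`,
#' a log-likelihood term rewarding fit plus a scale-free prior term rewarding
#' power-law degree structure. `epsilon` keeps the score finite for perfect
#' fits (RSS = 0).
#'
#' @param rss Nonnegative residual sum of squares.
#' @param log_prior Scale-free log-prior, `log(C^2)` (<= 0 or 0 when neutral).
#' @param epsilon Additive floor inside the log (default 1e-12).
#' @return Scalar score.
#' @export
posterior_score <- function(rss, log_prior, epsilon = 1e-12) {
  stopifnot(rss >= 0, epsilon > 0)
  -log(rss + epsilon) + log_prior
}

#' Boosting configuration
#'
#' Tuning parameters of [boosting_fit()].
#'
#' @param n_iterations Maximum boosting rounds per target gene (default 100).
#' @param shrinkage Step-size multiplier in (0, 1] (default 0.1).
#' @param lambda Reference scale-free exponent (default 2.5; see
#'   [scale_free_prior()]).
#' @param rss_epsilon Additive floor inside the log-likelihood (default
#'   1e-12).
#' @param coefficient_zero_tol Coefficients with absolute value at or below
#'   this are set to exactly 0 after fitting (default 1e-10).
#' @param seed Integer recorded with the fit. The fit itself is
#'   deterministic; the seed is carried for provenance with simulated inputs.
#' @return A list of class `boosting_config`.
#' @export
boosting_config <- function(n_iterations = 100L, shrinkage = 0.1,
                            lambda = 2.5, rss_epsilon = 1e-12,
                            coefficient_zero_tol = 1e-10, seed = 1L) {
  stopifnot(n_iterations >= 0, shrinkage > 0, shrinkage <= 1, lambda > 0,
            rss_epsilon > 0, coefficient_zero_tol >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 shrinkage = shrinkage, lambda = lambda,
                 rss_epsilon = rss_epsilon,
                 coefficient_zero_tol = coefficient_zero_tol,
                 seed = as.integer(seed)),
            class = "boosting_config")
}

#' Fit gene-gene regressions by posterior-score boosting
#'
#' Infers a sparse coefficient matrix by componentwise boosting: for each
#' target gene i (in input order), starting from a zero coefficient vector,
#' each round evaluates for every candidate predictor j != i the update
#' `beta[i, j] <- beta[i, j] + shrinkage * (x_j^T r_i)` (with `r_i` the
#' current residual of gene i) under the posterior score
#' `-log(RSS_i + epsilon) + log_prior`, where the scale-free log-prior is
#' computed on the full coefficient matrix with the candidate update in
#' place. The single best-scoring update is applied (ties broken by lowest
#' gene index); the target's boosting stops early when no update increases
#' its score. The coefficient matrix — and hence the degree distribution the
#' prior sees — is shared across targets and updated as fitting proceeds.
#'
#' @param expr A standardized [expression_matrix()]
#'   (see [standardize_expression()]); at least 2 genes and 3 samples.
#' @param config A [boosting_config()].
#' @param use_prior Set `FALSE` to force a neutral prior (`log_prior = 0`),
#'   reducing the objective to the pure likelihood term.
#'
#' @return An object of class `netsam_fit`: list with `beta` (p x p
#'   coefficient matrix, zero diagonal, entries with
#'   `|beta| <= coefficient_zero_tol` set to 0), `gene_ids`, `config`, and
#'   `trace` (tibble with one row per accepted update plus the initial state
#'   of each target: `gene`, `iteration`, `score`, `rss`, `log_prior`).
#' @seealso [build_network()] to binarize the fit into a network,
#'   [edge_scores()] for continuous per-pair evidence.
#' @export
#' @examples
#' sim <- simulation_config(n_genes = 20, n_samples = 30, target_edges = 30,
#'                          seed = 7)
#' net <- generate_topology(sim)
#' expr <- standardize_expression(generate_expression(net, sim))
#' fit <- boosting_fit(expr, boosting_config(n_iterations = 30))
#' fit
boosting_fit <- function(expr, config = boosting_config(), use_prior = TRUE) {
  x <- unclass(expr)[seq_len(nrow(expr)), , drop = FALSE]
  p <- nrow(x); n <- ncol(x)
  if (p < 2L || n < 3L) stop("need p >= 2 genes and n >= 3 samples", call. = FALSE)
  if (!is_standardized(x))
    stop("expression must be standardized (standardize_expression())",
         call. = FALSE)
  stopifnot(inherits(config, "boosting_config"))
  s <- config$shrinkage
  eps <- config$rss_epsilon
  gain <- s * (2 - s)

  beta <- matrix(0, p, p, dimnames = list(rownames(x), rownames(x)))
  d <- numeric(p)              # column sums of |beta|
  bins <- degree_bins(d)       # current integer degree bin per gene
  h <- tabulate(bins, nbins = max(64L, max(bins)))  # bin histogram

  cur_prior <- if (use_prior) prior_from_hist(h)$log_prior else 0

  # candidate prior for a histogram transition (move one gene ob -> nb)
  cand_prior <- function(ob, nb) {
    if (ob == nb) return(cur_prior)
    h2 <- h
    if (nb > length(h2)) h2 <- c(h2, numeric(nb - length(h2)))
    h2[ob] <- h2[ob] - 1L
    h2[nb] <- h2[nb] + 1L
    prior_from_hist(h2)$log_prior
  }

  n_max <- p * (config$n_iterations + 1L)
  trace_gene <- character(n_max); trace_iter <- integer(n_max)
  trace_score <- numeric(n_max); trace_rss <- numeric(n_max)
  trace_lp <- numeric(n_max); n_tr <- 0L
  push_trace <- function(g, it, sc, rs, lp) {
    n_tr <<- n_tr + 1L
    trace_gene[n_tr] <<- g; trace_iter[n_tr] <<- it
    trace_score[n_tr] <<- sc; trace_rss[n_tr] <<- rs; trace_lp[n_tr] <<- lp
  }

  for (i in seq_len(p)) {
    r <- x[i, ]
    rss <- sum(r^2)
    score <- -log(rss + eps) + cur_prior
    push_trace(rownames(x)[i], 0L, score, rss, cur_prior)

    iter <- 0L
    while (iter < config$n_iterations) {
      cvec <- as.vector(x %*% r)
      delta <- s * cvec
      rss_new <- rss - gain * cvec^2
      ll_new <- -log(pmax(rss_new, 0) + eps)

      if (use_prior) {
        bi <- beta[i, ]
        d_new <- d + abs(bi + delta) - abs(bi)
        nb <- degree_bins(d_new)
        lp_new <- rep(cur_prior, p)
        changed <- which(nb != bins)
        if (length(changed)) {
          key <- bins[changed] * 100000L + nb[changed]
          for (k in unique(key)) {
            sel <- changed[key == k]
            lp_new[sel] <- cand_prior(bins[sel[1L]], nb[sel[1L]])
          }
        }
      } else {
        lp_new <- rep(0, p)
      }

      sc <- ll_new + lp_new
      sc[i] <- -Inf
      j <- which.max(sc)       # first max: lowest-index tie-break
      if (!(sc[j] > score)) break

      beta[i, j] <- beta[i, j] + delta[j]
      r <- r - delta[j] * x[j, ]
      rss <- sum(r^2)
      if (use_prior) {
        d[j] <- d_new[j]
        if (nb[j] != bins[j]) {
          if (nb[j] > length(h)) h <- c(h, numeric(nb[j] - length(h)))
          h[bins[j]] <- h[bins[j]] - 1L
          h[nb[j]] <- h[nb[j]] + 1L
          bins[j] <- nb[j]
          cur_prior <- prior_from_hist(h)$log_prior
        }
      }
      score <- -log(rss + eps) + cur_prior
      iter <- iter + 1L
      push_trace(rownames(x)[i], iter, score, rss, cur_prior)
    }
  }

  keep <- seq_len(n_tr)
  beta[abs(beta) <= config$coefficient_zero_tol] <- 0
  structure(list(
    beta = beta, gene_ids = rownames(x), config = config,
    trace = tibble::tibble(gene = trace_gene[keep], iteration = trace_iter[keep],
                           score = trace_score[keep], rss = trace_rss[keep],
                           log_prior = trace_lp[keep])
  ), class = "netsam_fit")
}

#' @export
print.netsam_fit <- function(x, ...) {
  cat(sprintf("netsam_fit: %d genes, %d nonzero coefficients, %d boosting updates\n",
              length(x$gene_ids), sum(x$beta != 0),
              sum(x$trace$iteration > 0)))
  invisible(x)
}

#' @rdname glance.netsam_fit
#' @export
tidy.netsam_fit <- function(x, ...) {
  idx <- which(x$beta != 0, arr.ind = TRUE)
  out <- tibble::tibble(target = x$gene_ids[idx[, 1L]],
                        predictor = x$gene_ids[idx[, 2L]],
                        beta = x$beta[idx])
  dplyr::arrange(out, .data$target, .data$predictor)
}

#' Tidy and summarize a boosting fit
#'
#' `tidy()` returns the nonzero coefficients (`target`, `predictor`, `beta`);
#' `glance()` returns a one-row summary.
#'
#' @param x A `netsam_fit` from [boosting_fit()].
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.netsam_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids),
                 n_nonzero = sum(x$beta != 0),
                 n_updates = sum(x$trace$iteration > 0),
                 mean_iterations = mean(tapply(x$trace$iteration,
                                               x$trace$gene, max)),
                 final_log_prior = x$trace$log_prior[nrow(x$trace)])
}

#' Binarize a coefficient matrix into a network
#'
#' An undirected edge i--j is present when the coefficient product
#' `beta[i, j] * beta[j, i]` has nonzero sign, i.e. both directed
#' coefficients are nonzero (either polarity). With `rule = "same_sign"` the
#' stricter variant additionally requires the two coefficients to agree in
#' sign.
#'
#' @param fit A `netsam_fit` from [boosting_fit()], or a p x p coefficient
#'   matrix with gene IDs as dimnames.
#' @param rule `"nonzero"` (default) or `"same_sign"`.
#' @return A [gene_network()].
#' @export
build_network <- function(fit, rule = c("nonzero", "same_sign")) {
  rule <- match.arg(rule)
  beta <- if (inherits(fit, "netsam_fit")) fit$beta else as.matrix(fit)
  adj <- if (rule == "nonzero") {
    (beta != 0) & (t(beta) != 0)
  } else {
    beta * t(beta) > 0
  }
  diag(adj) <- FALSE
  gene_network(adj * 1L, rownames(beta))
}

#' Continuous per-pair edge evidence
#'
#' Scores each unordered gene pair by `min(|beta[i, j]|, |beta[j, i]|)` — a
#' pair is as credible as its weaker directed coefficient, consistent with
#' the binarization rule of [build_network()] (edge iff both directions are
#' nonzero).
#'
#' @param fit A `netsam_fit` or coefficient matrix.
#' @return A symmetric p x p numeric score matrix with zero diagonal.
#' @export
edge_scores <- function(fit) {
  beta <- if (inherits(fit, "netsam_fit")) fit$beta else as.matrix(fit)
  sc <- pmin(abs(beta), t(abs(beta)))
  diag(sc) <- 0
  sc
}
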