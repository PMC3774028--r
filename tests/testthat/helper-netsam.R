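# Shared fixtures and independent oracles.

# tiny expression matrix with named genes/samples
toy_expression <- function(values, genes = NULL, samples = NULL,
                           log_scale = TRUE) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, log_scale = log_scale)
}

# brute-force AUC: concordance probability over all (positive, negative) pairs
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct linear-solve GeneRank oracle on a small adjacency matrix
generank_solve <- function(adj, expression_change, damping) {
  p <- nrow(adj)
  e <- expression_change / sum(expression_change)
  deg <- colSums(adj)
  w <- adj / rep(pmax(deg, 1), each = p)
  w[, deg == 0] <- e
  as.vector(solve(diag(p) - damping * w, (1 - damping) * e))
}

# p orthonormal mean-zero rows of length n (requires n >= p + 1): the QR of
# centered columns stays inside the sum-zero subspace, so rows come out both
# unit-norm orthogonal and mean 0
orthonormal_rows <- function(p, n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm((p + 1) * n), p + 1, n)
    m <- m - rowMeans(m)
    q <- t(qr.Q(qr(t(m)))[, seq_len(p)])
    rownames(q) <- paste0("g", seq_len(p))
    q
  })
}

# signed edge-key helper
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
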