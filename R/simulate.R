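#' Benchmark simulation configuration
#'
#' Defaults emulate the standard SynTReN-style benchmark setting: 200 genes,
#' 100 samples per condition, roughly 500 true edges, and additive Gaussian
#' noise with sigma = 0.5. The differential extension rewires 10% of edges
#' between conditions and plants 20 differentially expressed genes with a
#' mean shift of 1.5 log2 units in case samples.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_samples Samples per condition (default 100).
#' @param target_edges Edge count of the base topology (default 500; must not
#'   exceed `n_genes * (n_genes - 1) / 2`).
#' @param noise_sigma Standard deviation of the additive Gaussian noise on
#'   non-root genes (default 0.5).
#' @param rewire_fraction Fraction of base edges removed (and replaced by an
#'   equal number of new edges) in the case condition (default 0.1).
#' @param n_de_genes Number of genes receiving a case-specific mean shift
#'   (default 20, capped at `n_genes`).
#' @param de_shift Mean shift in log2 units (default 1.5).
#' @param seed Integer seed; every generator is deterministic given the
#'   config.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_samples = 100L,
                              target_edges = 500L, noise_sigma = 0.5,
                              rewire_fraction = 0.1,
                              n_de_genes = min(20L, n_genes),
                              de_shift = 1.5, seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  target_edges <- as.integer(target_edges)
  stopifnot(n_genes >= 2, n_samples >= 2, target_edges >= 1,
            noise_sigma > 0, rewire_fraction >= 0, rewire_fraction <= 1,
            n_de_genes >= 0, n_de_genes <= n_genes)
  if (target_edges > n_genes * (n_genes - 1) / 2)
    stop("target_edges exceeds the number of gene pairs", call. = FALSE)
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 target_edges = target_edges, noise_sigma = noise_sigma,
                 rewire_fraction = rewire_fraction,
                 n_de_genes = as.integer(n_de_genes), de_shift = de_shift,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_gene_ids <- function(p) sprintf("g%03d", seq_len(p))

#' Generate a scale-free benchmark topology
#'
#' Preferential attachment: nodes are added one at a time and attach to
#' existing nodes with probability proportional to degree + 1, yielding a
#' right-skewed (power-law-like) degree distribution. The per-node edge
#' budget is chosen so the final graph has exactly `target_edges` edges
#' (no self-loops, no multi-edges); deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A [gene_network()].
#' @export
generate_topology <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$n_genes; m <- config$target_edges
  withr::with_seed(config$seed, {
    adj <- matrix(0L, p, p)
    deg <- integer(p)
    # node 1..2 seeded with one edge; nodes t = 3..p attach m_t edges each
    adj[1L, 2L] <- adj[2L, 1L] <- 1L
    deg[1:2] <- 1L
    remaining <- m - 1L
    for (t in seq_len(p)[-(1:2)]) {
      slots_left <- p - t + 1L
      # average edges still needed per incoming node, capped by availability
      m_t <- max(1L, as.integer(round(remaining / slots_left)))
      m_t <- min(m_t, t - 1L, remaining)
      if (m_t > 0L) {
        w <- deg[seq_len(t - 1L)] + 1
        nb <- sample.int(t - 1L, size = m_t, prob = w)  # weighted, no repeats
        adj[t, nb] <- 1L; adj[nb, t] <- 1L
        deg[nb] <- deg[nb] + 1L
        deg[t] <- m_t
        remaining <- remaining - m_t
      }
    }
    # top up with random non-edges if the budget was not exhausted
    while (remaining > 0L) {
      i <- sample.int(p, 1L)
      w <- (adj[i, ] == 0L) * (deg + 1)
      w[i] <- 0
      if (all(w == 0)) next
      j <- sample.int(p, 1L, prob = w)
      adj[i, j] <- adj[j, i] <- 1L
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      remaining <- remaining - 1L
    }
  })
  gene_network(adj, sim_gene_ids(p))
}

# Draw edge weights: uniform magnitude in [0.3, 0.9], random sign.
# Returns a weight matrix over the DAG orientation low-index -> high-index.
draw_weights <- function(adjacency) {
  idx <- which(upper.tri(adjacency) & adjacency == 1L, arr.ind = TRUE)
  w <- stats::runif(nrow(idx), 0.3, 0.9) *
    sample(c(-1, 1), nrow(idx), replace = TRUE)
  wm <- matrix(0, nrow(adjacency), ncol(adjacency))
  wm[idx] <- w
  wm
}

# Sample from the linear-Gaussian system induced by weights (parents = lower
# index): roots ~ N(0, 1); child j = sum_i w[i, j] x_i + N(0, sigma^2).
sample_linear_gaussian <- function(weights, n_samples, noise_sigma,
                                   gene_ids) {
  p <- nrow(weights)
  x <- matrix(0, p, n_samples)
  for (j in seq_len(p)) {
    parents <- which(weights[, j] != 0)
    if (length(parents) == 0L) {
      x[j, ] <- stats::rnorm(n_samples)
    } else {
      x[j, ] <- as.vector(crossprod(x[parents, , drop = FALSE],
                                    weights[parents, j])) +
        stats::rnorm(n_samples, sd = noise_sigma)
    }
  }
  rownames(x) <- gene_ids
  colnames(x) <- paste0("s", seq_len(n_samples))
  expression_matrix(x, log_scale = TRUE)
}

#' Generate expression data from a topology
#'
#' Orients the undirected topology acyclically (parents have lower node
#' index, the natural orientation of the preferential-attachment order),
#' assigns each edge a weight with magnitude uniform in [0.3, 0.9] and random
#' sign, and samples from the induced linear-Gaussian system: root genes are
#' N(0, 1) and each child is the weighted sum of its parents plus
#' N(0, `noise_sigma`^2). Values are treated as log2-scale intensities.
#'
#' @param network A [gene_network()].
#' @param config A [simulation_config()] (uses `n_samples`, `noise_sigma`,
#'   `seed`).
#' @return An [expression_matrix()] with `log_scale = TRUE` and the weight
#'   matrix attached as attribute `"weights"`.
#' @export
generate_expression <- function(network, config) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, {
    wm <- draw_weights(network$adjacency)
    x <- sample_linear_gaussian(wm, config$n_samples, config$noise_sigma,
                                network$gene_ids)
  })
  attr(x, "weights") <- wm
  x
}

#' Generate a case/control benchmark with known ground truth
#'
#' The control condition uses the base scale-free topology. The case
#' condition rewires `rewire_fraction` of the base edges: those edges are
#' removed and an equal number of new edges added; the removed (control-only)
#' and added (case-only) edges are the planted differential edges, tagged
#' `"negative"` and `"positive"` respectively. Shared edges keep identical
#' weights in both conditions. `n_de_genes` genes additionally receive a mean
#' shift of `de_shift` log2 units in case samples.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `case` and `control`
#'   ([expression_matrix()]s), `labels` (a [sample_labels()] tibble over the
#'   combined samples), and `truth`: a list with `control_network`,
#'   `case_network` ([gene_network()]s), `differential_edges` (signed edge
#'   tibble), `de_genes` (character vector), and `weights` (the shared weight
#'   matrix of the control condition).
#' @export
generate_case_control <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  base_net <- generate_topology(config)
  p <- config$n_genes
  adj_ctrl <- base_net$adjacency
  ids <- base_net$gene_ids

  withr::with_seed(config$seed + 2L, {
    pairs <- which(upper.tri(adj_ctrl) & adj_ctrl == 1L, arr.ind = TRUE)
    n_rewire <- as.integer(round(config$rewire_fraction * nrow(pairs)))
    if (config$rewire_fraction > 0 && n_rewire == 0L)
      stop("rewire_fraction yields zero rewired edges; use a larger network ",
           "or a larger fraction", call. = FALSE)
    drop_idx <- if (n_rewire > 0L) sample.int(nrow(pairs), n_rewire) else integer(0)

    adj_case <- adj_ctrl
    if (n_rewire > 0L) {
      dropped <- pairs[drop_idx, , drop = FALSE]
      adj_case[dropped] <- 0L
      adj_case[dropped[, c(2L, 1L), drop = FALSE]] <- 0L
      # add the same number of brand-new edges (absent from the base network)
      free <- which(upper.tri(adj_ctrl) & adj_ctrl == 0L, arr.ind = TRUE)
      added <- free[sample.int(nrow(free), n_rewire), , drop = FALSE]
      adj_case[added] <- 1L
      adj_case[added[, c(2L, 1L), drop = FALSE]] <- 1L
    } else {
      dropped <- added <- matrix(integer(0), 0L, 2L)
    }

    wm_ctrl <- draw_weights(adj_ctrl)
    wm_case <- wm_ctrl
    if (n_rewire > 0L) {
      lo_d <- pmin(dropped[, 1L], dropped[, 2L]); hi_d <- pmax(dropped[, 1L], dropped[, 2L])
      wm_case[cbind(lo_d, hi_d)] <- 0
      lo_a <- pmin(added[, 1L], added[, 2L]); hi_a <- pmax(added[, 1L], added[, 2L])
      wm_case[cbind(lo_a, hi_a)] <- stats::runif(n_rewire, 0.3, 0.9) *
        sample(c(-1, 1), n_rewire, replace = TRUE)
    }

    de_genes <- if (config$n_de_genes > 0L)
      sort(sample.int(p, config$n_de_genes)) else integer(0)

    ctrl_x <- sample_linear_gaussian(wm_ctrl, config$n_samples,
                                     config$noise_sigma, ids)
    case_x <- sample_linear_gaussian(wm_case, config$n_samples,
                                     config$noise_sigma, ids)
  })

  xc <- unclass(case_x)[seq_len(p), , drop = FALSE]
  if (length(de_genes)) xc[de_genes, ] <- xc[de_genes, ] + config$de_shift
  colnames(xc) <- paste0("case_", seq_len(config$n_samples))
  case_x <- expression_matrix(xc, log_scale = TRUE)
  xk <- unclass(ctrl_x)[seq_len(p), , drop = FALSE]
  colnames(xk) <- paste0("ctrl_", seq_len(config$n_samples))
  ctrl_x <- expression_matrix(xk, log_scale = TRUE)

  case_net <- gene_network(adj_case, ids)
  sign_edge <- function(mat, sgn) {
    if (nrow(mat) == 0L)
      return(tibble::tibble(gene_a = character(), gene_b = character(),
                            sign = character()))
    tibble::tibble(gene_a = ids[pmin(mat[, 1L], mat[, 2L])],
                   gene_b = ids[pmax(mat[, 1L], mat[, 2L])],
                   sign = sgn)
  }
  diff_edges <- dplyr::arrange(
    dplyr::bind_rows(sign_edge(added, "positive"), sign_edge(dropped, "negative")),
    .data$gene_a, .data$gene_b)

  labels <- sample_labels(c(colnames(case_x), colnames(ctrl_x)),
                          rep(c("case", "control"),
                              each = config$n_samples))

  list(case = case_x, control = ctrl_x, labels = labels,
       truth = list(control_network = base_net, case_network = case_net,
                    differential_edges = diff_edges,
                    de_genes = ids[de_genes], weights = wm_ctrl))
}
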