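#' GeneRank scores
#'
#' PageRank-style prioritization biased toward differentially expressed
#' genes: solves the fixed point
#' `r = (1 - damping) * e + damping * W %*% r`, where `e` is the
#' differential-expression vector normalized to sum 1 and `W` is the
#' column-degree-normalized adjacency (columns of isolated genes are replaced
#' by `e`, the standard dangling-node fix, keeping `W` column-stochastic).
#' With damping 0 the score is purely the expression change; with damping
#' near 1 it is purely network connectivity; the default 0.5 weighs both
#' equally. Scores are nonnegative and sum to 1.
#'
#' @param network A [gene_network()] or [differential_network()].
#' @param expression_change Nonnegative per-gene vector aligned to the
#'   network's genes (e.g. `abs(log2 fold change)`); not all zero. Either a
#'   named/plain numeric vector in network gene order or a data frame with
#'   columns `gene` and a single numeric column.
#' @param damping Controlling parameter in `[0, 1)` (default 0.5).
#' @param tolerance Max-norm convergence tolerance of the fixed-point
#'   iteration (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A tibble with columns `gene`, `generank_score` (sums to 1),
#'   `generank_rank` (1 = best, ties broken by gene ID).
#' @export
generank <- function(network, expression_change, damping = 0.5,
                     tolerance = 1e-10, max_iter = 10000L) {
  stopifnot(damping >= 0, damping < 1, tolerance > 0, max_iter >= 1)
  ids <- network$gene_ids
  ec <- align_gene_vector(expression_change, ids)
  if (any(ec < 0)) stop("expression_change must be nonnegative", call. = FALSE)
  if (all(ec == 0)) stop("expression_change must not be all zero", call. = FALSE)
  e <- ec / sum(ec)

  adj <- network_adjacency(network)
  deg <- colSums(adj)
  p <- length(ids)
  w <- adj / rep(pmax(deg, 1), each = p)
  dangling <- deg == 0
  if (any(dangling)) w[, dangling] <- e

  r <- rep(1 / p, p)
  for (it in seq_len(max_iter)) {
    r_new <- (1 - damping) * e + damping * as.vector(w %*% r)
    if (max(abs(r_new - r)) < tolerance) { r <- r_new; break }
    r <- r_new
    if (it == max_iter)
      stop("GeneRank did not converge within max_iter iterations", call. = FALSE)
  }
  out <- tibble::tibble(gene = ids, generank_score = r)
  out$generank_rank <- rank_desc(out$generank_score, out$gene)
  out
}

# dense adjacency for either network class
network_adjacency <- function(network) {
  if (inherits(network, "differential_network")) {
    p <- length(network$gene_ids)
    adj <- matrix(0, p, p, dimnames = list(network$gene_ids, network$gene_ids))
    if (nrow(network$edges)) {
      adj[cbind(network$edges$gene_a, network$edges$gene_b)] <- 1
      adj[cbind(network$edges$gene_b, network$edges$gene_a)] <- 1
    }
    adj
  } else {
    network$adjacency + 0
  }
}

align_gene_vector <- function(v, ids) {
  if (is.data.frame(v)) {
    val_col <- setdiff(names(v), "gene")[1L]
    miss <- setdiff(ids, v$gene)
    if (length(miss))
      stop("expression_change missing genes: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    return(as.numeric(v[[val_col]][match(ids, v$gene)]))
  }
  if (!is.null(names(v))) {
    miss <- setdiff(ids, names(v))
    if (length(miss))
      stop("expression_change missing genes: ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    return(as.numeric(v[ids]))
  }
  if (length(v) != length(ids))
    stop("expression_change length must match the number of genes", call. = FALSE)
  as.numeric(v)
}

# dense rank, 1 = largest value, ties by gene ID
rank_desc <- function(score, gene) {
  ord <- order(-score, gene)
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

#' Rank genes by differential degree
#'
#' @param diff A [differential_network()] (or [gene_network()]).
#' @param genes Optional subset of genes to rank (e.g. hubs); defaults to all
#'   network genes.
#' @return A tibble with columns `gene`, `degree`, `degree_rank` sorted by
#'   decreasing degree, ties broken by gene ID.
#' @export
degree_ranking <- function(diff, genes = NULL) {
  deg <- node_degrees(diff)
  if (!is.null(genes)) {
    miss <- setdiff(genes, deg$gene)
    if (length(miss))
      stop("genes not in the network: ", paste(utils::head(miss, 5L),
                                               collapse = ", "), call. = FALSE)
    deg <- deg[match(genes, deg$gene), ]
  }
  if (!nrow(deg)) stop("empty network", call. = FALSE)
  deg$degree_rank <- rank_desc(deg$degree, deg$gene)
  dplyr::arrange(deg, .data$degree_rank)
}

#' Intersect the top k genes of two rankings
#'
#' @param ranking1,ranking2 Rankings: either character vectors of gene IDs in
#'   rank order, or tibbles with a `gene` column ordered best-first (e.g.
#'   outputs of [generank()] arranged by rank, or [degree_ranking()]).
#' @param k Number of top genes to take from each ranking (default 10).
#' @return Character vector: the genes in both top-k lists, ordered by their
#'   position in `ranking1`.
#' @export
intersect_top_k <- function(ranking1, ranking2, k = 10L) {
  stopifnot(k >= 1)
  g1 <- ranked_genes(ranking1)
  g2 <- ranked_genes(ranking2)
  top1 <- utils::head(g1, k)
  top2 <- utils::head(g2, k)
  top1[top1 %in% top2]
}

ranked_genes <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    rk_col <- intersect(c("generank_rank", "degree_rank", "rank"), names(x))
    if (length(rk_col)) return(x$gene[order(x[[rk_col[1L]]])])
    return(x$gene)
  }
  stop("ranking must be a character vector or a tibble with a gene column",
       call. = FALSE)
}

#' Prioritize differential-network hubs
#'
#' Runs the two rankings of the prioritization stage on the full differential
#' network — GeneRank (connectivity plus differential expression) and plain
#' differential degree — reads them off for the hub genes, and intersects the
#' two top-k hub lists into the candidate signature.
#'
#' @param diff A [differential_network()].
#' @param hubs Hub table from [identify_hubs()] (or a character vector of hub
#'   genes).
#' @param de A `netsam_de` tibble; `abs(log2 fold change)` =
#'   `log2(fold_change)` is used as the differential-expression vector.
#' @param damping GeneRank controlling parameter (default 0.5).
#' @param top_k Top-list size for the intersection (default 10).
#' @return A list of class `netsam_ranking`: `ranking` (tibble over hub
#'   genes: `gene`, `generank_score`, `generank_rank`, `degree`,
#'   `degree_rank`, re-ranked within hubs), `signature` (character vector),
#'   and `parameters`.
#' @export
prioritize_hubs <- function(diff, hubs, de, damping = 0.5, top_k = 10L) {
  hub_genes <- if (is.data.frame(hubs)) hubs$gene else as.character(hubs)
  if (!length(hub_genes)) stop("no hub genes to prioritize", call. = FALSE)
  ec <- tibble::tibble(gene = de$gene, change = log2(de$fold_change))
  gr <- generank(diff, ec, damping = damping)
  dr <- degree_ranking(diff)

  out <- tibble::tibble(gene = hub_genes)
  out$generank_score <- gr$generank_score[match(hub_genes, gr$gene)]
  out$degree <- dr$degree[match(hub_genes, dr$gene)]
  out$generank_rank <- rank_desc(out$generank_score, out$gene)
  out$degree_rank <- rank_desc(as.numeric(out$degree), out$gene)
  out <- dplyr::arrange(out, .data$generank_rank)

  sig <- intersect_top_k(out$gene[order(out$generank_rank)],
                         out$gene[order(out$degree_rank)], k = top_k)
  structure(list(ranking = out, signature = sig,
                 parameters = list(damping = damping, top_k = top_k)),
            class = "netsam_ranking")
}

#' @export
print.netsam_ranking <- function(x, ...) {
  cat(sprintf("netsam_ranking: %d hubs, signature of %d gene(s): %s\n",
              nrow(x$ranking), length(x$signature),
              paste(x$signature, collapse = ", ")))
  invisible(x)
}

#' @rdname glance.netsam_ranking
#' @export
tidy.netsam_ranking <- function(x, ...) x$ranking

#' Tidy and summarize a hub prioritization
#'
#' `tidy()` returns the per-hub ranking table; `glance()` a one-row summary.
#'
#' @param x A `netsam_ranking` from [prioritize_hubs()].
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.netsam_ranking <- function(x, ...) {
  tibble::tibble(n_hubs = nrow(x$ranking),
                 n_signature = length(x$signature),
                 damping = x$parameters$damping,
                 top_k = x$parameters$top_k)
}
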