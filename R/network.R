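#' Construct a gene network
#'
#' An undirected, unweighted network over a fixed gene universe, stored as a
#' binary symmetric adjacency matrix with zero diagonal.
#'
#' @param adjacency Square 0/1 matrix (symmetric, zero diagonal). Rownames are
#'   taken as gene IDs unless `gene_ids` is given.
#' @param gene_ids Character vector of gene IDs.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(adjacency, gene_ids = rownames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  p <- nrow(adjacency)
  if (ncol(adjacency) != p) stop("adjacency must be square", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match the adjacency dimension", call. = FALSE)
  if (!all(adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (!identical(adjacency, t(adjacency)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adjacency) != 0L))
    stop("adjacency must have a zero diagonal (no self-edges)", call. = FALSE)
  dimnames(adjacency) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, adjacency = adjacency),
            class = "gene_network")
}

#' Build a gene network from an edge table
#'
#' @param edges Data frame with gene ID columns `gene_a`, `gene_b` (extra
#'   columns ignored).
#' @param gene_ids Gene universe; defaults to the genes present in `edges`.
#' @return A [gene_network()].
#' @export
network_from_edges <- function(edges, gene_ids = NULL) {
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(a, b)))
  if (any(!c(a, b) %in% gene_ids))
    stop("edge endpoints outside the gene universe", call. = FALSE)
  if (any(a == b)) stop("self-edges are not allowed", call. = FALSE)
  p <- length(gene_ids)
  adj <- matrix(0L, p, p, dimnames = list(gene_ids, gene_ids))
  adj[cbind(a, b)] <- 1L
  adj[cbind(b, a)] <- 1L
  gene_network(adj, gene_ids)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$gene_ids), n_edges(x)))
  invisible(x)
}

#' Number of edges in a network
#' @param network A [gene_network()] or [differential_network()].
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  if (inherits(network, "differential_network")) return(nrow(network$edges))
  sum(network$adjacency) %/% 2L
}

#' Per-gene degree
#'
#' @param network A [gene_network()] or [differential_network()].
#' @return A tibble with columns `gene`, `degree` (all genes in the universe,
#'   isolated genes included with degree 0).
#' @export
node_degrees <- function(network) {
  if (inherits(network, "differential_network")) {
    deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                        levels = network$gene_ids))
    return(tibble::tibble(gene = network$gene_ids, degree = as.integer(deg)))
  }
  tibble::tibble(gene = network$gene_ids,
                 degree = as.integer(rowSums(network$adjacency)))
}

# Canonical edge tibble (endpoints in lexicographic order, rows sorted).
edge_table <- function(network) {
  idx <- which(upper.tri(network$adjacency) & network$adjacency == 1L,
               arr.ind = TRUE)
  a <- network$gene_ids[idx[, 1L]]
  b <- network$gene_ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- tibble::tibble(gene_a = a, gene_b = b)
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Construct a differential network
#'
#' Edges present in only one of two condition-specific networks, each tagged
#' `"positive"` (case-specific, inducible) or `"negative"` (control-specific,
#' suppressive).
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `sign`
#'   (`"positive"`/`"negative"`); endpoints distinct.
#' @param gene_ids Gene universe.
#' @return An object of class `differential_network` with fields `gene_ids`,
#'   `edges` (canonicalized tibble) and `degree` (named integer vector).
#' @export
differential_network <- function(edges, gene_ids) {
  gene_ids <- as.character(gene_ids)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
    if (any(a == b)) stop("self-edges are not allowed", call. = FALSE)
    if (any(!c(a, b) %in% gene_ids))
      stop("edge endpoints outside the gene universe", call. = FALSE)
    if (any(!edges$sign %in% c("positive", "negative")))
      stop("edge sign must be 'positive' or 'negative'", call. = FALSE)
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- tibble::tibble(gene_a = a, gene_b = b, sign = edges$sign)
    if (anyDuplicated(paste(a, b)))
      stop("an edge may carry only one sign tag", call. = FALSE)
    edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  } else {
    edges <- tibble::tibble(gene_a = character(), gene_b = character(),
                            sign = character())
  }
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = gene_ids))
  structure(list(gene_ids = gene_ids, edges = edges,
                 degree = stats::setNames(as.integer(deg), gene_ids)),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("differential_network: %d genes, %d edges (%d positive, %d negative)\n",
              length(x$gene_ids), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Write a network as a TSV edge list
#'
#' One line per undirected edge, endpoints in lexicographic order, with a
#' third `sign` column for differential networks (SIF-compatible). Reading the
#' file back with [read_edge_list()] reproduces the edge set exactly.
#'
#' @param network A [gene_network()] or [differential_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  if (inherits(network, "differential_network")) {
    readr::write_tsv(network$edges, path)
  } else {
    readr::write_tsv(edge_table(network), path)
  }
  invisible(path)
}

#' Read a TSV edge list
#'
#' @param path Path written by [write_edge_list()] (2-column plain network or
#'   3-column signed differential network).
#' @param gene_ids Gene universe; defaults to the genes present in the file.
#' @return A [gene_network()] or [differential_network()] according to the
#'   column count.
#' @export
read_edge_list <- function(path, gene_ids = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) >= 3L) {
    names(df)[1:3] <- c("gene_a", "gene_b", "sign")
    if (is.null(gene_ids)) gene_ids <- sort(unique(c(df$gene_a, df$gene_b)))
    differential_network(df[1:3], gene_ids)
  } else {
    names(df)[1:2] <- c("gene_a", "gene_b")
    network_from_edges(df, gene_ids)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.differential_network
#' @export
tidy.gene_network <- function(x, ...) edge_table(x)

#' Tidy a network into an edge tibble
#'
#' @param x A [gene_network()] or [differential_network()].
#' @param ... Unused.
#' @return A tibble of edges (`gene_a`, `gene_b`, and `sign` for differential
#'   networks), endpoints in lexicographic order.
#' @export
tidy.differential_network <- function(x, ...) x$edges

#' @rdname glance.differential_network
#' @export
glance.gene_network <- function(x, ...) {
  deg <- node_degrees(x)$degree
  tibble::tibble(n_genes = length(x$gene_ids), n_edges = n_edges(x),
                 max_degree = if (length(deg)) max(deg) else 0L,
                 median_degree = stats::median(deg))
}

#' One-row network summaries
#'
#' @param x A [gene_network()] or [differential_network()].
#' @param ... Unused.
#' @return A one-row tibble of node/edge counts (and sign counts for
#'   differential networks).
#' @export
glance.differential_network <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids), n_edges = nrow(x$edges),
                 n_positive = sum(x$edges$sign == "positive"),
                 n_negative = sum(x$edges$sign == "negative"),
                 max_degree = if (length(x$degree)) max(x$degree) else 0L)
}
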