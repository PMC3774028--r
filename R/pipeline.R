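#' Run the full differential-network pipeline
#'
#' The five-stage analysis in one call:
#' 1. differential expression (Student's t-test + fold change) and DE-gene
#'    filtering;
#' 2. per-condition network inference by posterior-score boosting on the DE
#'    panel;
#' 3. network subtraction into the signed differential network;
#' 4. hub identification (degree and p-value thresholds);
#' 5. hub prioritization by GeneRank and differential degree, intersected
#'    into the candidate signature.
#'
#' @param expr A log2-scale [expression_matrix()] with case and control
#'   samples.
#' @param labels A [sample_labels()] tibble.
#' @param fc_threshold,p_threshold DE-filter thresholds (defaults 2, 0.01).
#' @param boosting A [boosting_config()].
#' @param min_degree,max_p Hub thresholds (defaults 5, 0.01).
#' @param damping,top_k Prioritization parameters (defaults 0.5, 10).
#' @return A list of class `netsam_result` with elements `de`, `de_genes`,
#'   `case_fit`, `control_fit`, `case_network`, `control_network`,
#'   `differential_network`, `hubs`, `ranking` (`NULL` when no hubs pass),
#'   `signature`, `parameters`.
#' @export
#' @examples
#' sim <- generate_case_control(simulation_config(n_genes = 40, n_samples = 40,
#'                                                target_edges = 80,
#'                                                n_de_genes = 15, seed = 3))
#' expr <- cbind_expression(sim$case, sim$control)
#' res <- netsam(expr, sim$labels,
#'               boosting = boosting_config(n_iterations = 40),
#'               min_degree = 2)
#' glance(res)
netsam <- function(expr, labels, fc_threshold = 2, p_threshold = 0.01,
                   boosting = boosting_config(), min_degree = 5L,
                   max_p = 0.01, damping = 0.5, top_k = 10L) {
  de <- differential_expression(expr, labels, fc_threshold = fc_threshold,
                                p_threshold = p_threshold)
  de_genes <- filter_de_genes(de, fc_threshold, p_threshold)
  panel <- subset_genes(expr, de_genes)   # aborts on an empty panel
  if (length(de_genes) < 2L)
    stop("fewer than 2 genes passed the differential-expression filter; ",
         "network inference needs at least 2", call. = FALSE)

  case_expr <- standardize_expression(split_by_group(panel, labels, "case"))
  ctrl_expr <- standardize_expression(split_by_group(panel, labels, "control"))
  shared <- intersect(rownames(case_expr), rownames(ctrl_expr))
  case_fit <- boosting_fit(subset_genes(case_expr, shared), boosting)
  ctrl_fit <- boosting_fit(subset_genes(ctrl_expr, shared), boosting)

  case_net <- build_network(case_fit)
  ctrl_net <- build_network(ctrl_fit)
  diff_net <- subtract_networks(case_net, ctrl_net)

  hubs <- identify_hubs(diff_net, de, min_degree = min_degree, max_p = max_p)
  ranking <- NULL
  signature <- character(0)
  if (nrow(hubs)) {
    ranking <- prioritize_hubs(diff_net, hubs, de, damping = damping,
                               top_k = top_k)
    signature <- ranking$signature
  }

  structure(list(
    de = de, de_genes = de_genes,
    case_fit = case_fit, control_fit = ctrl_fit,
    case_network = case_net, control_network = ctrl_net,
    differential_network = diff_net,
    hubs = hubs, ranking = ranking, signature = signature,
    parameters = list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                      boosting = boosting, min_degree = min_degree,
                      max_p = max_p, damping = damping, top_k = top_k)
  ), class = "netsam_result")
}

#' @export
print.netsam_result <- function(x, ...) {
  cnt <- classify_interactions(x$differential_network)
  cat("netsam_result\n")
  cat(sprintf("  DE genes: %d of %d\n", length(x$de_genes), nrow(x$de)))
  cat(sprintf("  case/control edges: %d / %d\n",
              n_edges(x$case_network), n_edges(x$control_network)))
  cat(sprintf("  differential edges: %d (%d positive, %d negative)\n",
              cnt$n_total, cnt$n_positive, cnt$n_negative))
  cat(sprintf("  hubs: %d; signature: %s\n", nrow(x$hubs),
              if (length(x$signature)) paste(x$signature, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @rdname glance.netsam_result
#' @export
tidy.netsam_result <- function(x, ...) {
  if (is.null(x$ranking)) {
    return(tibble::tibble(gene = character(), generank_score = numeric(),
                          degree = integer(), generank_rank = integer(),
                          degree_rank = integer(), in_signature = logical()))
  }
  out <- x$ranking$ranking
  out$in_signature <- out$gene %in% x$signature
  out
}

#' Tidy and summarize a pipeline result
#'
#' `tidy()` returns the per-hub ranking table with an `in_signature` flag;
#' `glance()` a one-row summary of every stage.
#'
#' @param x A `netsam_result` from [netsam()].
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.netsam_result <- function(x, ...) {
  cnt <- classify_interactions(x$differential_network)
  tibble::tibble(
    n_genes = nrow(x$de), n_de_genes = length(x$de_genes),
    n_case_edges = n_edges(x$case_network),
    n_control_edges = n_edges(x$control_network),
    n_differential_edges = cnt$n_total,
    n_positive = cnt$n_positive, n_negative = cnt$n_negative,
    n_hubs = nrow(x$hubs), n_signature = length(x$signature)
  )
}
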