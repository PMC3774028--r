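#' Subtract two condition-specific networks
#'
#' The differential network is the symmetric difference of the case and
#' control edge sets: edges present in exactly one condition. Case-specific
#' edges are tagged `"positive"` (inducible epistasis), control-specific
#' edges `"negative"` (suppression); edges shared by both conditions are the
#' trivial interactions removed by the subtraction. Degrees are recomputed on
#' the differential edge set.
#'
#' @param case_net,control_net [gene_network()]s over identical gene IDs in
#'   identical order.
#' @return A [differential_network()].
#' @export
#' @examples
#' tri <- network_from_edges(tibble::tibble(gene_a = c("A", "B", "C"),
#'                                          gene_b = c("B", "C", "A")))
#' one <- network_from_edges(tibble::tibble(gene_a = "A", gene_b = "B"),
#'                           gene_ids = c("A", "B", "C"))
#' subtract_networks(tri, one)
subtract_networks <- function(case_net, control_net) {
  if (!identical(case_net$gene_ids, control_net$gene_ids))
    stop("case and control networks must share the same gene universe ",
         "(same IDs, same order)", call. = FALSE)
  a <- case_net$adjacency; b <- control_net$adjacency
  diff <- a != b
  idx <- which(upper.tri(diff) & diff, arr.ind = TRUE)
  ids <- case_net$gene_ids
  edges <- tibble::tibble(
    gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
    sign = ifelse(a[idx] == 1L, "positive", "negative")
  )
  differential_network(edges, ids)
}

#' Count differential interactions by sign
#'
#' @param diff A [differential_network()].
#' @return A one-row tibble with `n_total`, `n_positive`, `n_negative`
#'   (`n_total == n_positive + n_negative`).
#' @export
classify_interactions <- function(diff) {
  stopifnot(inherits(diff, "differential_network"))
  tibble::tibble(n_total = nrow(diff$edges),
                 n_positive = sum(diff$edges$sign == "positive"),
                 n_negative = sum(diff$edges$sign == "negative"))
}

#' Identify differential-network hubs
#'
#' A hub is a gene with differential degree at or above `min_degree` and
#' differential-expression p-value at or below `max_p` (both thresholds
#' inclusive). The p-value is the per-gene case/control test from
#' [differential_expression()] — the only per-gene significance computed
#' upstream.
#'
#' @param diff A [differential_network()].
#' @param de A `netsam_de` tibble covering every gene of the differential
#'   network.
#' @param min_degree Minimum differential degree (default 5).
#' @param max_p Maximum DE p-value (default 0.01).
#' @return A tibble with columns `gene`, `degree`, `p_value`, sorted by
#'   decreasing degree, ties broken by gene ID.
#' @export
identify_hubs <- function(diff, de, min_degree = 5L, max_p = 0.01) {
  stopifnot(inherits(diff, "differential_network"),
            min_degree >= 1, max_p > 0, max_p <= 1)
  missing <- setdiff(diff$gene_ids, de$gene)
  if (length(missing))
    stop("genes missing from the differential-expression table: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  p <- de$p_value[match(diff$gene_ids, de$gene)]
  keep <- diff$degree >= min_degree & p <= max_p
  out <- tibble::tibble(gene = diff$gene_ids[keep],
                        degree = unname(diff$degree[keep]),
                        p_value = p[keep])
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene)
}
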