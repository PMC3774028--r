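#' Per-gene differential expression between case and control
#'
#' First stage of the pipeline: each gene is tested for a case/control mean
#' difference with a two-sample Student's t-test (equal-variance by default,
#' two-sided), and a symmetric linear-scale fold change is computed from the
#' group means, `2^|mean_case - mean_control|`, assuming log2-scale input.
#' Genes with zero pooled variance but unequal means get `p_value = 0` (an
#' infinitely strong separation at machine precision); this is reported via a
#' message.
#'
#' @param expr A log2-scale [expression_matrix()].
#' @param labels Sample labels from [sample_labels()]; both groups need at
#'   least 2 samples.
#' @param fc_threshold Fold-change threshold (linear scale) used to set
#'   `pass_filter`; default 2.
#' @param p_threshold P-value threshold used to set `pass_filter`;
#'   default 0.01.
#' @param var_equal Use the pooled-variance Student's t-test (default); set
#'   `FALSE` for Welch's unequal-variance test.
#'
#' @return A tibble of class `netsam_de` with columns `gene`, `mean_case`,
#'   `mean_control`, `fold_change`, `t_statistic`, `p_value`, `pass_filter`
#'   (in input gene order). A gene passes when `fold_change > fc_threshold`
#'   and `p_value < p_threshold`, both strict.
#' @export
#' @examples
#' sim <- generate_case_control(simulation_config(n_genes = 40, n_samples = 30,
#'                                                target_edges = 60, seed = 1))
#' expr <- cbind_expression(sim$case, sim$control)
#' de <- differential_expression(expr, sim$labels)
#' head(de)
differential_expression <- function(expr, labels, fc_threshold = 2,
                                    p_threshold = 0.01, var_equal = TRUE) {
  if (!is_log_scale(expr))
    stop("differential_expression expects log2-scale input ",
         "(read with log_transform = TRUE or set the log_scale flag)",
         call. = FALSE)
  grp <- check_labels(expr, labels, min_per_group = 2L)
  x <- unclass(expr)
  case <- x[, grp == "case", drop = FALSE]
  ctrl <- x[, grp == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)

  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  tstat <- (m1 - m2) / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  # degenerate genes: no variance at all
  zero_se <- !is.finite(tstat)
  eq <- zero_se & (m1 == m2)
  sep <- zero_se & (m1 != m2)
  tstat[eq] <- 0; pval[eq] <- 1
  tstat[sep] <- sign(m1 - m2)[sep] * Inf; pval[sep] <- 0
  if (any(sep))
    message(sum(sep), " gene(s) with zero pooled variance and unequal means; ",
            "p_value set to 0")

  fc <- 2^abs(m1 - m2)
  out <- tibble::tibble(
    gene = rownames(x), mean_case = unname(m1), mean_control = unname(m2),
    fold_change = unname(fc), t_statistic = unname(tstat),
    p_value = unname(pval),
    pass_filter = unname(fc > fc_threshold & pval < p_threshold)
  )
  class(out) <- c("netsam_de", class(out))
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Select differentially expressed genes
#'
#' Applies the two-criterion filter: fold change strictly greater than
#' `fc_threshold` and p-value strictly less than `p_threshold`.
#'
#' @param de A `netsam_de` tibble from [differential_expression()].
#' @param fc_threshold Linear-scale fold-change cutoff (default 2).
#' @param p_threshold P-value cutoff (default 0.01).
#' @param adjust Multiple-testing adjustment applied to `p_value` before
#'   filtering (a `stats::p.adjust` method); `"none"` by default.
#' @return Character vector of gene IDs in input order (possibly empty).
#' @export
filter_de_genes <- function(de, fc_threshold = 2, p_threshold = 0.01,
                            adjust = "none") {
  stopifnot(fc_threshold > 0, p_threshold > 0)
  p <- stats::p.adjust(de$p_value, method = adjust)
  de$gene[de$fold_change > fc_threshold & p < p_threshold]
}

#' Restrict an expression matrix to a gene panel
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of gene IDs to keep.
#' @return The restricted [expression_matrix()] (gene order as in `genes`).
#' @export
subset_genes <- function(expr, genes) {
  if (!length(genes))
    stop("empty gene panel: no genes passed the differential-expression ",
         "filter; relax the thresholds", call. = FALSE)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not in the expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  expression_matrix(unclass(expr)[genes, , drop = FALSE],
                    log_scale = is_log_scale(expr))
}

#' Column-bind two expression matrices over the same genes
#'
#' @param a,b [expression_matrix()] objects with identical gene IDs and the
#'   same `log_scale` flag; sample IDs must not clash.
#' @return The combined [expression_matrix()].
#' @export
cbind_expression <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("gene universes differ", call. = FALSE)
  if (is_log_scale(a) != is_log_scale(b))
    stop("log_scale flags differ", call. = FALSE)
  expression_matrix(cbind(unclass(a)[seq_len(nrow(a)), , drop = FALSE],
                          unclass(b)[seq_len(nrow(b)), , drop = FALSE]),
                    log_scale = is_log_scale(a))
}
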