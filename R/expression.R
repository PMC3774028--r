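#' Construct an expression matrix
#'
#' The core data container: a numeric genes x samples matrix with unique gene
#' IDs as rownames, sample IDs as colnames, and a `log_scale` flag recording
#' whether values are on the log2 scale (downstream differential-expression
#' fold changes assume log2 input).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene IDs (defaults to rownames).
#' @param sample_ids Character vector of sample IDs (defaults to colnames).
#' @param log_scale Logical; `TRUE` if values are log2 intensities.
#'
#' @return A matrix of class `expression_matrix` with a `log_scale` attribute.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_matrix(m, log_scale = TRUE)
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              log_scale = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length must equal the number of rows", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length must equal the number of columns", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "log_scale") <- isTRUE(log_scale)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (log_scale = %s)\n",
              nrow(x), ncol(x), attr(x, "log_scale")))
  y <- unclass(x)
  attr(y, "log_scale") <- NULL
  print(utils::head(y[, seq_len(min(ncol(y), 6L)), drop = FALSE]), ...)
  invisible(x)
}

is_log_scale <- function(expr) isTRUE(attr(expr, "log_scale"))

#' Read an expression matrix from TSV
#'
#' Expects tab-separated text with gene IDs in the first column and a header
#' row of sample IDs. Values must be numeric and finite; duplicate gene IDs
#' are rejected. With `log_transform = TRUE` all values must be strictly
#' positive and are replaced by `log2(value)`.
#'
#' @param path Path to a TSV file.
#' @param log_transform Apply a log2 transform on load.
#' @param transpose Set `TRUE` if the file stores samples as rows.
#'
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, log_transform = FALSE, transpose = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) stop("expression file needs an ID column plus >= 1 sample column",
                          call. = FALSE)
  ids <- df[[1L]]
  if (anyNA(ids)) stop("missing gene ID in expression file", call. = FALSE)
  values <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(ids, names(df)[-1L]))
  if (anyNA(values))
    stop("non-numeric or missing expression values in ", path, call. = FALSE)
  if (transpose) values <- t(values)
  if (log_transform) {
    if (any(values <= 0))
      stop("log2 transform requested but values are not strictly positive",
           call. = FALSE)
    values <- log2(values)
  }
  expression_matrix(values, log_scale = log_transform)
}

#' Write an expression matrix to TSV
#'
#' Full-precision text output; [read_expression()] on the result reproduces
#' the values bit-exactly.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(unclass(expr)[seq_len(nrow(expr)), , drop = FALSE],
                          .name_repair = "minimal")
  df <- tibble::add_column(df, gene = rownames(expr), .before = 1L)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read case/control sample labels
#'
#' Two-column TSV (`sample_id`, `group`) with `group` in `{case, control}`.
#'
#' @param path Path to a TSV label file.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(df)[1:2] <- c("sample_id", "group")
  sample_labels(df$sample_id, df$group)
}

#' Construct a sample-label table
#'
#' @param sample_id Character vector of sample IDs.
#' @param group Per-sample group, `"case"` or `"control"`.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
sample_labels <- function(sample_id, group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(sample_id = as.character(sample_id), group = group)
}

# Check labels cover the expression samples and both groups are usable.
check_labels <- function(expr, labels, min_per_group = 2L) {
  missing <- setdiff(colnames(expr), labels$sample_id)
  if (length(missing))
    stop("unlabeled samples: ", paste(missing, collapse = ", "), call. = FALSE)
  grp <- labels$group[match(colnames(expr), labels$sample_id)]
  n_case <- sum(grp == "case"); n_ctrl <- sum(grp == "control")
  if (n_case < min_per_group || n_ctrl < min_per_group)
    stop(sprintf("need >= %d samples per group (case: %d, control: %d)",
                 min_per_group, n_case, n_ctrl), call. = FALSE)
  grp
}

#' Split an expression matrix by group
#'
#' @param expr An [expression_matrix()].
#' @param labels Label tibble from [sample_labels()] or [read_labels()].
#' @param group `"case"` or `"control"`.
#' @return The [expression_matrix()] restricted to the group's samples.
#' @export
split_by_group <- function(expr, labels, group = c("case", "control")) {
  group <- match.arg(group)
  grp <- check_labels(expr, labels, min_per_group = 1L)
  expression_matrix(unclass(expr)[, grp == group, drop = FALSE],
                    log_scale = is_log_scale(expr))
}
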