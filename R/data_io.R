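#' Construct an expression matrix
#'
#' The central data container of the package: a genes x samples numeric
#' matrix with unique identifiers on both axes and a declared value scale.
#' Raw sequencing counts (`"counts"`), log2 counts-per-million (`"logcpm"`),
#' gene-wise z-scores (`"zscore"`) and anything else (`"other"`) are
#' distinguished so downstream stages can refuse inputs on the wrong scale.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param value_scale One of `"counts"`, `"logcpm"`, `"zscore"`, `"other"`.
#' @return The matrix with its `value_scale` attribute set.
#' @export
expression_matrix <- function(values,
                              value_scale = c("counts", "logcpm", "zscore", "other")) {
  value_scale <- match.arg(value_scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs rownames (genes) and colnames (samples)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate gene ID: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop("duplicate sample ID: ", dup, call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("expression matrix needs >= 1 gene and >= 2 samples", call. = FALSE)
  }
  if (value_scale == "counts" && any(values < 0, na.rm = TRUE)) {
    stop("value_scale = \"counts\" requires non-negative entries", call. = FALSE)
  }
  attr(values, "value_scale") <- value_scale
  values
}

#' Value scale of an expression matrix
#' @param x An expression matrix created by [expression_matrix()] or one of
#'   the transforms.
#' @return A string: the declared scale, `"other"` when undeclared.
#' @export
value_scale <- function(x) {
  vs <- attr(x, "value_scale")
  if (is.null(vs)) "other" else vs
}

.na_tokens <- c("na", "nan", "")

#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs (the
#' Xena-style layout). Recognised missing-value tokens are `NA`, `NaN` and
#' the empty string, case-insensitively. Any other non-numeric cell is a
#' hard error reported with its row/column coordinates.
#'
#' @param path Path to a TSV file.
#' @param value_scale Declared scale of the stored values (see
#'   [expression_matrix()]).
#' @return An expression matrix.
#' @export
read_expression <- function(path,
                            value_scale = c("counts", "logcpm", "zscore", "other")) {
  value_scale <- match.arg(value_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 3) stop("expected >= 1 gene ID column and >= 2 samples",
                          call. = FALSE)
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  is_na_token <- matrix(tolower(trimws(cells)) %in% .na_tokens, nrow = nrow(cells))
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is_na_token, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell \"%s\" at gene row %d, sample column %d (%s)",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2],
                 colnames(raw)[-1][bad[1, 2]]), call. = FALSE)
  }
  num[is_na_token] <- NA_real_
  rownames(num) <- gene_ids
  colnames(num) <- colnames(raw)[-1]
  X <- expression_matrix(num, value_scale)
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(X), ncol(X), path))
  X
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header row of sample IDs, first column
#' `gene_id`. Round-trips conforming matrices up to float formatting.
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- tibble::as_tibble(x, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Construct two-group sample labels
#'
#' @param sample_id Character vector of sample IDs.
#' @param group Vector of `"control"` / `"case"` assignments, same length.
#' @param positive_group Group treated as positive (diseased) when computing
#'   classification metrics; default `"case"`.
#' @return A tibble with columns `sample_id`, `group` and a
#'   `positive_group` attribute; class `group_labels`.
#' @export
group_labels <- function(sample_id, group, positive_group = "case") {
  group <- as.character(group)
  if (length(sample_id) != length(group)) {
    stop("sample_id and group differ in length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ID: ", sample_id[duplicated(sample_id)][1],
         call. = FALSE)
  }
  bad <- setdiff(unique(group), c("control", "case"))
  if (length(bad) > 0) {
    stop("group values must be \"control\"/\"case\"; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!positive_group %in% c("control", "case")) {
    stop("positive_group must be \"control\" or \"case\"", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(sample_id), group = group)
  attr(out, "positive_group") <- positive_group
  class(out) <- c("group_labels", class(out))
  out
}

#' Read a two-column phenotype TSV into group labels
#'
#' The file must have columns `sample_id` and a label column; rows whose
#' label matches `control_label` map to `"control"`, rows matching
#' `case_label` map to `"case"`, anything else is an error listing the
#' offending rows.
#'
#' @param path Path to a two-column TSV (sample_id, label).
#' @param control_label,case_label Label strings in the file to map to the
#'   two groups (e.g. `"ADENO"` and `"SCC"`).
#' @return A [group_labels()] tibble.
#' @export
read_groups <- function(path, control_label, case_label) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("expected two columns: sample_id, label", call. = FALSE)
  lab <- raw[[2]]
  unknown <- which(!(lab %in% c(control_label, case_label)))
  if (length(unknown) > 0) {
    stop(sprintf("label(s) matching neither \"%s\" nor \"%s\" at row(s) %s (e.g. \"%s\")",
                 control_label, case_label,
                 paste(head(unknown, 5), collapse = ", "), lab[unknown[1]]),
         call. = FALSE)
  }
  group <- ifelse(lab == control_label, "control", "case")
  if (!any(group == "control")) stop("no control samples (label \"",
                                     control_label, "\")", call. = FALSE)
  if (!any(group == "case")) stop("no case samples (label \"",
                                  case_label, "\")", call. = FALSE)
  gl <- group_labels(raw[[1]], group)
  message(sprintf("read %d samples: %d control, %d case",
                  nrow(gl), sum(group == "control"), sum(group == "case")))
  gl
}

#' Write group labels as TSV
#' @param groups A [group_labels()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  readr::write_tsv(tibble::as_tibble(groups), path, progress = FALSE)
  invisible(path)
}

#' Align an expression matrix with group labels by sample ID
#'
#' Intersects the sample IDs of the two inputs (ID-based, never positional),
#' drops samples present on only one side (logged), and never reorders
#' genes. Sample order follows the expression matrix.
#'
#' @param x Expression matrix.
#' @param groups A [group_labels()] tibble.
#' @return A list with elements `expression` and `groups`, restricted to the
#'   shared samples.
#' @export
align_samples <- function(x, groups) {
  shared <- intersect(colnames(x), groups$sample_id)
  if (length(shared) < 2) stop("fewer than 2 shared samples", call. = FALSE)
  dropped <- (ncol(x) - length(shared)) + (nrow(groups) - length(shared))
  if (dropped > 0) {
    message(sprintf("dropped %d sample(s) absent from one side", dropped))
  }
  keep <- colnames(x)[colnames(x) %in% shared]
  x2 <- x[, keep, drop = FALSE]
  attr(x2, "value_scale") <- value_scale(x)
  g2 <- groups[match(keep, groups$sample_id), ]
  attr(g2, "positive_group") <- attr(groups, "positive_group")
  class(g2) <- class(groups)
  if (!all(c("control", "case") %in% g2$group)) {
    stop("a group is empty after alignment", call. = FALSE)
  }
  list(expression = x2, groups = g2)
}

# split sample indices (columns of an aligned matrix) by group
.group_index <- function(x, groups) {
  idx <- match(colnames(x), groups$sample_id)
  if (anyNA(idx)) stop("matrix and labels are not aligned; call align_samples()",
                       call. = FALSE)
  g <- groups$group[idx]
  list(control = which(g == "control"), case = which(g == "case"))
}
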