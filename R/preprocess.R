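#' Pre-filter genes: drop all-zero rows and handle missing values
#'
#' Genes whose row is entirely zero are removed. Genes containing missing
#' values are removed (`drop_gene`, default) or have their missing entries
#' set to zero (`impute_zero`).
#'
#' @param x Expression matrix.
#' @param drop_na_policy `"drop_gene"` or `"impute_zero"`.
#' @return A list: `expression` (filtered matrix) and `report`, a one-row
#'   tibble with counts `n_input_genes`, `n_dropped_all_zero`,
#'   `n_dropped_na`, `n_dropped_constant` (0 here; filled by
#'   [standardize_genes()]) and `n_output_genes`.
#' @export
prefilter <- function(x, drop_na_policy = c("drop_gene", "impute_zero")) {
  drop_na_policy <- match.arg(drop_na_policy)
  vs <- value_scale(x)
  n_in <- nrow(x)
  has_na <- rowSums(is.na(x)) > 0
  n_na <- 0L
  if (any(has_na)) {
    if (drop_na_policy == "drop_gene") {
      n_na <- sum(has_na)
      x <- x[!has_na, , drop = FALSE]
    } else {
      x[is.na(x)] <- 0
    }
  }
  all_zero <- rowSums(x != 0, na.rm = TRUE) == 0
  n_zero <- sum(all_zero)
  x <- x[!all_zero, , drop = FALSE]
  if (nrow(x) == 0) stop("empty matrix after prefilter", call. = FALSE)
  attr(x, "value_scale") <- vs
  report <- tibble::tibble(
    n_input_genes = n_in,
    n_dropped_all_zero = as.integer(n_zero),
    n_dropped_na = as.integer(n_na),
    n_dropped_constant = 0L,
    n_output_genes = nrow(x)
  )
  list(expression = x, report = report)
}

#' Gene-wise standardization to z-scores
#'
#' Each gene row is centred and scaled to unit sample standard deviation
#' (denominator S - 1). Rows with zero variance carry no co-expression
#' information and are dropped; their count is attached as the
#' `n_dropped_constant` attribute.
#'
#' @param x Expression matrix with >= 2 samples.
#' @return A z-scored expression matrix (`value_scale = "zscore"`) with
#'   attribute `n_dropped_constant`.
#' @export
standardize_genes <- function(x) {
  if (ncol(x) < 2) stop("standardization needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  keep <- s > 0
  n_const <- sum(!keep)
  if (!any(keep)) stop("empty matrix after dropping constant genes", call. = FALSE)
  z <- (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
  out <- expression_matrix(z, "zscore")
  attr(out, "n_dropped_constant") <- as.integer(n_const)
  if (n_const > 0) message(sprintf("dropped %d constant gene(s)", n_const))
  out
}

#' Log2 counts-per-million transform
#'
#' The voom-style count transform: for count c in a library of size L,
#' `y = log2((c + prior_count) / (L + 1) * 1e6)`. Strictly increasing in the
#' count within a column; the small prior count keeps zeros finite.
#'
#' @param x Expression matrix on the `"counts"` scale.
#' @param prior_count Pseudo-count added to every cell (default 0.5).
#' @return Expression matrix on the `"logcpm"` scale.
#' @export
log_cpm <- function(x, prior_count = 0.5) {
  if (value_scale(x) != "counts") {
    stop("log_cpm expects value_scale = \"counts\"", call. = FALSE)
  }
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop("library size 0 for sample ", colnames(x)[which(lib == 0)[1]],
         call. = FALSE)
  }
  y <- log2(sweep(x + prior_count, 2, lib + 1, "/") * 1e6)
  expression_matrix(y, "logcpm")
}

#' Voom-style precision weights from the mean-variance trend
#'
#' Fits a two-group mean model per gene, then the lowess trend of
#' sqrt(residual sd) against mean log-CPM. Each observation's predicted
#' sqrt-sd is read off the trend at its fitted value (clamped to the
#' trend's range) and inverted to a precision weight `predicted^-4`.
#'
#' @param y Expression matrix on the `"logcpm"` scale.
#' @param groups A [group_labels()] tibble aligned with `y`.
#' @param lowess_span Smoother span (default 0.5).
#' @return A genes x samples matrix of positive finite weights.
#' @export
voom_weights <- function(y, groups, lowess_span = 0.5) {
  if (nrow(y) < 10) {
    stop("voom_weights needs >= 10 genes to estimate the mean-variance trend",
         call. = FALSE)
  }
  gi <- .group_index(y, groups)
  fit <- fit_two_group(y, groups)
  gene_mean <- rowMeans(y)
  sqrt_sd <- sqrt(sqrt(fit$s2))
  lo <- lowess(gene_mean, sqrt_sd, f = lowess_span)
  # fitted value of each observation = its group's mean for that gene
  fitted <- matrix(0, nrow(y), ncol(y), dimnames = dimnames(y))
  fitted[, gi$control] <- fit$mean_control
  fitted[, gi$case] <- fit$mean_case
  fitted[fitted < min(lo$x)] <- min(lo$x)
  fitted[fitted > max(lo$x)] <- max(lo$x)
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted), ties = mean,
                 rule = 2)$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^-4, nrow(y), ncol(y), dimnames = dimnames(y))
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}
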