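#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); invariant
#' to strictly monotone transforms of either vector. Returns `NA` when
#' either vector is constant (the correlation is undefined there).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A number in `[-1, 1]`, or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Score gene modules by average pairwise Spearman correlation
#'
#' For every cluster of a partition, computes the mean Spearman correlation
#' over all unordered within-cluster gene pairs (pairs with undefined
#' correlation — a constant gene — are excluded from the mean and counted).
#' Singleton clusters get `NA`. Up-/down-regulated gene counts per cluster
#' are tallied from the DE table when given.
#'
#' @param x Expression matrix whose rows cover the partition's objects
#'   (ranks are unaffected by gene-wise standardization, so any monotone
#'   per-gene transform of the data gives the same scores).
#' @param p A [partition()] of (a subset of) the genes in `x`.
#' @param de Optional [moderated_de()] table supplying per-gene `status`.
#' @return A `module_scores` tibble: `cluster_id`, `n_genes`, `n_up`,
#'   `n_down`, `n_pairs_excluded`, `avg_spearman`.
#' @export
score_modules <- function(x, p, de = NULL) {
  missing <- setdiff(p$object_ids, rownames(x))
  if (length(missing) > 0) {
    stop("partition objects absent from the matrix: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  status <- NULL
  if (!is.null(de)) status <- de$status[match(p$object_ids, de$gene_id)]
  rows <- lapply(seq_len(p$k), function(cl) {
    genes <- p$object_ids[p$labels == cl]
    n_up <- if (is.null(status)) NA_integer_ else
      sum(status[p$labels == cl] == "up", na.rm = TRUE)
    n_down <- if (is.null(status)) NA_integer_ else
      sum(status[p$labels == cl] == "down", na.rm = TRUE)
    if (length(genes) < 2) {
      return(tibble::tibble(cluster_id = cl, n_genes = length(genes),
                            n_up = n_up, n_down = n_down,
                            n_pairs_excluded = 0L, avg_spearman = NA_real_))
    }
    rho <- suppressWarnings(
      cor(t(x[genes, , drop = FALSE]), method = "spearman"))
    vals <- rho[lower.tri(rho)]
    excl <- sum(is.na(vals))
    avg <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    tibble::tibble(cluster_id = cl, n_genes = length(genes), n_up = n_up,
                   n_down = n_down, n_pairs_excluded = as.integer(excl),
                   avg_spearman = avg)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("module_scores", class(out))
  out
}

#' Pick the best-scoring module as the gene signature
#'
#' The signature is the gene set of the module with the maximum average
#' pairwise Spearman correlation; ties are broken by larger module size,
#' then smaller cluster index. Modules with undefined score (singletons)
#' are never selectable.
#'
#' @param scores A [score_modules()] tibble.
#' @param p The [partition()] the scores were computed from.
#' @return A `gene_signature` list: `gene_ids`, `source_cluster`, `score`.
#' @export
pick_signature <- function(scores, p) {
  ok <- scores[!is.na(scores$avg_spearman), ]
  if (nrow(ok) == 0) stop("no scorable module (all singletons)", call. = FALSE)
  ok <- ok[order(-ok$avg_spearman, -ok$n_genes, ok$cluster_id), ]
  best <- ok$cluster_id[1]
  structure(list(
    gene_ids = p$object_ids[p$labels == best],
    source_cluster = best,
    score = ok$avg_spearman[1]
  ), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d genes from cluster %d (avg Spearman %.3f)\n",
              length(x$gene_ids), x$source_cluster, x$score))
  cat(paste(strwrap(paste(x$gene_ids, collapse = ", "), 70), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Write a signature gene list (one gene per line)
#' @param sig A `gene_signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  writeLines(sig$gene_ids, path)
  invisible(path)
}
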