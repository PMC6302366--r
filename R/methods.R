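#' Tidy a DE result
#' @param x A `de_result` from [moderated_de()].
#' @param ... Unused.
#' @return The per-gene tibble (one row per gene).
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' One-row summary of a DE result
#' @param x A `de_result`.
#' @param ... Unused.
#' @return Tibble with gene counts and the empirical-Bayes prior.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_ns = sum(x$status == "ns"),
    d0 = attr(x, "d0"),
    s0_sq = attr(x, "s0_sq")
  )
}

#' Tidy a Pareto ranking
#' @param x A `pareto_result`.
#' @param ... Unused.
#' @return Tibble of Pareto-optimal K with total dominance and rank.
#' @export
tidy.pareto_result <- function(x, ...) {
  tibble::tibble(k = x$pareto_k, total_dominance = as.numeric(x$rank_key),
                 rank = seq_along(x$pareto_k),
                 selected = x$pareto_k == x$selected_k)
}

#' One-row summary of a Pareto ranking
#' @param x A `pareto_result`.
#' @param ... Unused.
#' @return Tibble with `selected_k` and the Pareto-set size.
#' @export
glance.pareto_result <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k,
                 n_pareto = length(x$pareto_k),
                 n_candidates = length(x$k_values))
}

#' Tidy a CV report (one row per repeat)
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The per-repeat tibble.
#' @export
tidy.cv_report <- function(x, ...) x$per_repeat

#' One-row summary of a CV report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with mean and sd of the four metrics.
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    sensitivity = s$mean[s$metric == "sensitivity"],
    specificity = s$mean[s$metric == "specificity"],
    precision = s$mean[s$metric == "precision"],
    accuracy = s$mean[s$metric == "accuracy"],
    sd_accuracy = s$sd[s$metric == "accuracy"]
  )
}

#' Tidy an NSC model (per-gene shrinkage state)
#' @param x An `nsc_model`.
#' @param ... Unused.
#' @return Tibble with per-gene standardized deviations before and after
#'   shrinkage.
#' @export
tidy.nsc_model <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_ids,
    d_control = x$d[, "control"],
    d_case = x$d[, "case"],
    d_shrunk_control = x$d_shrunk[, "control"],
    d_shrunk_case = x$d_shrunk[, "case"],
    active = rowSums(x$d_shrunk != 0) > 0
  )
}

#' Volcano plot of a DE result
#'
#' Minus-log10 p against log2 fold change, coloured by volcano status,
#' with the filter thresholds drawn.
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  fc_hi <- attr(object, "fc_hi") %||% 2
  fc_lo <- attr(object, "fc_lo") %||% 0.5
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                               colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = log2(c(fc_lo, fc_hi)), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#d62728", down = "#1f77b4",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = expression(-log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stability-objective profiles across candidate K
#'
#' One line per objective (algorithm x index) against the candidate number
#' of clusters.
#'
#' @param object An `objective_matrix` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.objective_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"k",
                              names_to = "objective", values_to = "score") |>
    tidyr::separate_wider_delim("objective", ".",
                                names = c("algorithm", "index"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$score,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "candidate number of clusters K",
                  y = "bootstrap stability") +
    ggplot2::theme_minimal()
}

#' Classification metrics across CV repeats
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot (one point per repeat and metric, with the mean).
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_repeat,
                              c("sensitivity", "specificity", "precision",
                                "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "#d62728",
                          size = 3, shape = 18) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "repeated-CV value") +
    ggplot2::theme_minimal()
}

#' PCA scatter of clustered genes
#'
#' Projects the gene rows onto the first two principal components and
#' colours them by cluster membership — a quick visual check that the
#' extracted modules separate.
#'
#' @param x Numeric matrix (genes x samples), covering the partition.
#' @param p A [partition()].
#' @return A ggplot.
#' @export
plot_gene_pca <- function(x, p) {
  m <- x[p$object_ids, , drop = FALSE]
  pc <- stats::prcomp(m, rank. = 2)
  df <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                       cluster = factor(p$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster") +
    ggplot2::theme_minimal()
}
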