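#' Per-gene two-group fit
#'
#' Computes per gene the (optionally weighted) group means, the log2 fold
#' change (case minus control; the input must already be on a log2 scale)
#' and the residual variance on S - 2 degrees of freedom.
#'
#' @param y Expression matrix on a log2 scale (log-CPM or pre-normalized).
#' @param groups A [group_labels()] tibble aligned with `y`; both groups
#'   need >= 2 samples.
#' @param weights Optional genes x samples matrix of positive precision
#'   weights (e.g. from [voom_weights()]). Unit weights reproduce the
#'   unweighted fit.
#' @return A tibble with columns `gene_id`, `mean_control`, `mean_case`,
#'   `log2fc`, `s2`, `df_residual`, plus `v` (the per-gene contrast variance
#'   factor, `1/n1 + 1/n2` when unweighted).
#' @export
fit_two_group <- function(y, groups, weights = NULL) {
  gi <- .group_index(y, groups)
  n1 <- length(gi$control)
  n2 <- length(gi$case)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs >= 2 samples (got ", n1, " control, ", n2, " case)",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  stopifnot(all(dim(weights) == dim(y)), all(weights > 0))
  wc <- weights[, gi$control, drop = FALSE]
  wk <- weights[, gi$case, drop = FALSE]
  sw_c <- rowSums(wc)
  sw_k <- rowSums(wk)
  m_c <- rowSums(y[, gi$control, drop = FALSE] * wc) / sw_c
  m_k <- rowSums(y[, gi$case, drop = FALSE] * wk) / sw_k
  r_c <- y[, gi$control, drop = FALSE] - m_c
  r_k <- y[, gi$case, drop = FALSE] - m_k
  df <- n1 + n2 - 2
  s2 <- (rowSums(wc * r_c^2) + rowSums(wk * r_k^2)) / df
  tibble::tibble(
    gene_id = rownames(y),
    mean_control = unname(m_c),
    mean_case = unname(m_k),
    log2fc = unname(m_k - m_c),
    s2 = unname(s2),
    df_residual = df,
    v = unname(1 / sw_c + 1 / sw_k)
  )
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks each gene's residual variance toward a pooled prior variance
#' estimated from the whole ensemble: the prior (d0, s0^2) comes from
#' fitting a scaled F distribution to the observed variances by the
#' method of moments on log variances (digamma/trigamma inversion, via
#' `limma::fitFDist`), and the posterior variance is
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`. When the variances are
#' (near-)identical the prior degrees of freedom are infinite and
#' `s2_tilde` collapses to `s0^2` — that is a valid limit, not an error.
#'
#' @param s2 Per-gene residual variances (>= 10 positive values required).
#' @param df Residual degrees of freedom (scalar).
#' @return A list: `d0` (prior df, possibly `Inf`), `s0_sq` (prior
#'   variance) and `s2_tilde` (moderated variances, same order as `s2`).
#' @export
ebayes_moderate <- function(s2, df) {
  if (sum(s2 > 0, na.rm = TRUE) < 10) {
    stop("need >= 10 genes with positive variance to estimate the prior",
         call. = FALSE)
  }
  fd <- tryCatch(limma::fitFDist(s2, df1 = df),
                 error = function(e) list(scale = mean(s2), df2 = Inf))
  d0 <- fd$df2
  s0_sq <- fd$scale
  if (!is.finite(s0_sq) || s0_sq <= 0) {
    s0_sq <- mean(s2[s2 > 0])
    d0 <- Inf
  }
  s2_tilde <- shrink_var(s2, df, d0, s0_sq)
  list(d0 = d0, s0_sq = s0_sq, s2_tilde = s2_tilde)
}

#' Posterior variance under a known prior
#'
#' @param s2 Per-gene variances.
#' @param df Residual degrees of freedom.
#' @param d0 Prior degrees of freedom (may be `Inf` or 0).
#' @param s0_sq Prior variance.
#' @return Moderated variances `(d0 * s0_sq + df * s2) / (d0 + df)`.
#' @export
shrink_var <- function(s2, df, d0, s0_sq) {
  if (is.infinite(d0)) return(rep(s0_sq, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0_sq + df * s2) / (d0 + df)
}

#' Moderated two-group differential-expression test with volcano bi-filter
#'
#' Fits per-gene group means, moderates the variances with
#' [ebayes_moderate()], forms the moderated t statistic
#' `t = log2fc / sqrt(s2_tilde * v)` with p-values from a t distribution on
#' `d0 + df` degrees of freedom (two-sided), and classifies genes as
#' up-/down-regulated by the volcano bi-filter: up if `p < alpha` and fold
#' change `> fc_hi`, down if `p < alpha` and fold change `< fc_lo`, `ns`
#' otherwise. Raw p-values drive the filter (BH-adjusted q-values are
#' reported alongside; set `use_q = TRUE` to filter on them instead).
#'
#' @param y Expression matrix on a log2 scale.
#' @param groups A [group_labels()] tibble aligned with `y`.
#' @param weights Optional precision-weight matrix.
#' @param alpha P-value threshold (default 0.05).
#' @param fc_hi,fc_lo Fold-change thresholds (defaults 2 and 0.5); fold
#'   change is `2^log2fc` of the group means on the log scale.
#' @param use_q Filter on BH-adjusted q-values instead of raw p (default
#'   `FALSE`).
#' @return A `de_result` tibble with columns `gene_id`, `mean_control`,
#'   `mean_case`, `log2fc`, `fold_change`, `s2`, `s2_tilde`, `t_mod`, `p`,
#'   `q_bh`, `status`; prior estimates are attached as attributes `d0` and
#'   `s0_sq`.
#' @export
moderated_de <- function(y, groups, weights = NULL, alpha = 0.05,
                         fc_hi = 2, fc_lo = 0.5, use_q = FALSE) {
  fit <- fit_two_group(y, groups, weights)
  eb <- ebayes_moderate(fit$s2, fit$df_residual[1])
  t_mod <- fit$log2fc / sqrt(eb$s2_tilde * fit$v)
  df_total <- eb$d0 + fit$df_residual[1]
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod)] <- NA_real_
  q <- p.adjust(p, method = "BH")
  fc <- 2^fit$log2fc
  p_eff <- if (use_q) q else p
  status <- dplyr::case_when(
    p_eff < alpha & fc > fc_hi ~ "up",
    p_eff < alpha & fc < fc_lo ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::tibble(
    gene_id = fit$gene_id,
    mean_control = fit$mean_control,
    mean_case = fit$mean_case,
    log2fc = fit$log2fc,
    fold_change = fc,
    s2 = fit$s2,
    s2_tilde = eb$s2_tilde,
    t_mod = t_mod,
    p = p,
    q_bh = q,
    status = status
  )
  attr(out, "d0") <- eb$d0
  attr(out, "s0_sq") <- eb$s0_sq
  attr(out, "alpha") <- alpha
  attr(out, "fc_hi") <- fc_hi
  attr(out, "fc_lo") <- fc_lo
  class(out) <- c("de_result", class(out))
  out
}

#' Split a DE table into up- and down-regulated gene lists
#'
#' @param de A [moderated_de()] table (or any tibble with `gene_id`, `p`,
#'   `fold_change`).
#' @param alpha,fc_hi,fc_lo Volcano thresholds; defaults mirror
#'   [moderated_de()].
#' @return A list with character vectors `up` and `down`, in input gene
#'   order.
#' @export
volcano_filter <- function(de, alpha = 0.05, fc_hi = 2, fc_lo = 0.5) {
  up <- de$gene_id[!is.na(de$p) & de$p < alpha & de$fold_change > fc_hi]
  down <- de$gene_id[!is.na(de$p) & de$p < alpha & de$fold_change < fc_lo]
  list(up = up, down = down)
}
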