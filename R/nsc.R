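# class-wise per-gene statistics shared by fitting and the delta grid
.nsc_stats <- function(x, y) {
  gi <- .group_index(x, y)
  n1 <- length(gi$control)
  n2 <- length(gi$case)
  if (n1 < 2 || n2 < 2) {
    stop("each class needs >= 2 training samples (got ", n1, " control, ",
         n2, " case)", call. = FALSE)
  }
  n <- n1 + n2
  cent <- cbind(control = rowMeans(x[, gi$control, drop = FALSE]),
                case = rowMeans(x[, gi$case, drop = FALSE]))
  overall <- rowMeans(x)
  ss <- rowSums((x[, gi$control, drop = FALSE] - cent[, "control"])^2) +
    rowSums((x[, gi$case, drop = FALSE] - cent[, "case"])^2)
  s <- sqrt(ss / (n - 2))
  s0 <- median(s)
  mk <- c(control = sqrt(1 / n1 - 1 / n), case = sqrt(1 / n2 - 1 / n))
  d <- sweep(cent - overall, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  list(centroids = cent, overall = overall, s = s, s0 = s0, mk = mk, d = d,
       priors = c(control = n1 / n, case = n2 / n), n = n)
}

#' Fit a nearest-shrunken-centroid (NSC) classifier
#'
#' Per gene i and class k, the standardized centroid deviation
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` — with pooled
#' within-class sd `s_i`, fudge constant `s0 = median(s_i)` and
#' `m_k = sqrt(1/n_k - 1/n)` — is soft-thresholded by `delta`:
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`. Shrunken class centroids
#' are `xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik`; genes whose
#' deviations shrink to zero in both classes drop out of the classifier.
#' Class priors are the empirical class frequencies.
#'
#' @param x Signature-genes x training-samples matrix (log scale).
#' @param y A [group_labels()] tibble aligned with the columns of `x`;
#'   both classes need >= 2 samples.
#' @param delta Non-negative shrinkage threshold.
#' @return An `nsc_model` object.
#' @export
fit_nsc <- function(x, y, delta = 0) {
  stopifnot(delta >= 0)
  st <- .nsc_stats(x, y)
  d_shrunk <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  scale <- st$mk[col(d_shrunk)] * (st$s + st$s0)
  shrunken <- st$overall + matrix(scale, nrow(st$d)) * d_shrunk
  dimnames(shrunken) <- dimnames(st$centroids)
  structure(list(
    gene_ids = rownames(x),
    classes = c("control", "case"),
    centroids = st$centroids,
    overall = st$overall,
    s = st$s, s0 = st$s0, mk = st$mk,
    d = st$d, d_shrunk = d_shrunk,
    shrunken_centroids = shrunken,
    priors = st$priors,
    delta = delta,
    positive_group = attr(y, "positive_group") %||% "case"
  ), class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  active <- sum(rowSums(x$d_shrunk != 0) > 0)
  cat(sprintf("<nsc_model> %d genes (%d surviving shrinkage at delta = %.3g); priors %.2f/%.2f\n",
              length(x$gene_ids), active, x$delta,
              x$priors["control"], x$priors["case"]))
  invisible(x)
}

#' Predict sample classes from an NSC model
#'
#' Discriminant score for class k of a sample x is
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`;
#' the predicted class minimizes it, with exact ties resolved to the
#' control class.
#'
#' @param object An `nsc_model`.
#' @param newdata Genes x samples matrix (same genes as the model) or a
#'   single sample vector.
#' @param ... Unused.
#' @return A tibble: `sample_id`, `score_control`, `score_case`, `class`.
#' @export
predict.nsc_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
  if (nrow(newdata) != length(object$gene_ids)) {
    stop("newdata has ", nrow(newdata), " genes; model expects ",
         length(object$gene_ids), call. = FALSE)
  }
  denom <- (object$s + object$s0)^2
  score <- vapply(object$classes, function(k) {
    colSums((newdata - object$shrunken_centroids[, k])^2 / denom) -
      2 * log(object$priors[k])
  }, numeric(ncol(newdata)))
  score <- matrix(score, ncol = 2, dimnames = list(NULL, object$classes))
  cls <- unname(ifelse(score[, "case"] < score[, "control"], "case", "control"))
  tibble::tibble(
    sample_id = colnames(newdata) %||% as.character(seq_len(ncol(newdata))),
    score_control = score[, "control"],
    score_case = score[, "case"],
    class = cls
  )
}

# stratified fold assignment: within each class, samples (ordered by ID, so
# the assignment is a function of IDs, not of column positions) are shuffled
# and dealt out round-robin, so every fold gets its share of the minority
# class
.stratified_folds <- function(ids, group, folds, seed) {
  fold <- integer(length(group))
  withr::with_seed(seed, {
    for (g in sort(unique(group))) {
      idx <- which(group == g)
      idx <- idx[order(ids[idx])]
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Choose the shrinkage threshold by stratified cross-validation
#'
#' Evaluates a grid of `n_delta` thresholds from 0 to the largest
#' standardized centroid deviation `max |d_ik|` (computed on the full
#' input) by stratified k-fold cross-validation, and returns the LARGEST
#' delta attaining the minimum CV error — the most parsimonious model at
#' equal error, the usual NSC convention.
#'
#' @param x Genes x samples matrix.
#' @param y Aligned [group_labels()].
#' @param n_delta Grid size (default 30).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A list: `delta_star`, and `cv_error_curve` (tibble with `delta`,
#'   `errors`, `error_rate`).
#' @export
cv_select_delta <- function(x, y, n_delta = 30, folds = 10, seed = 1) {
  full <- .nsc_stats(x, y)
  grid <- seq(0, max(abs(full$d)), length.out = n_delta)
  g <- y$group[match(colnames(x), y$sample_id)]
  if (min(table(g)) < 2) stop("minority class smaller than 2", call. = FALSE)
  fold <- .stratified_folds(colnames(x), g, folds, seed)
  errors <- numeric(length(grid))
  for (f in sort(unique(fold))) {
    test <- fold == f
    xtr <- x[, !test, drop = FALSE]
    ytr <- y[y$sample_id %in% colnames(xtr), ]
    st <- .nsc_stats(xtr, ytr)
    denom <- (st$s + st$s0)^2
    xte <- x[, test, drop = FALSE]
    truth <- g[test]
    for (di in seq_along(grid)) {
      dsh <- sign(st$d) * pmax(abs(st$d) - grid[di], 0)
      scale <- st$mk[col(dsh)] * (st$s + st$s0)
      shr <- st$overall + matrix(scale, nrow(dsh)) * dsh
      sc_ctrl <- colSums((xte - shr[, 1])^2 / denom) - 2 * log(st$priors[1])
      sc_case <- colSums((xte - shr[, 2])^2 / denom) - 2 * log(st$priors[2])
      pred <- ifelse(sc_case < sc_ctrl, "case", "control")
      errors[di] <- errors[di] + sum(pred != truth)
    }
  }
  best <- min(errors)
  delta_star <- max(grid[errors == best])
  list(delta_star = delta_star,
       cv_error_curve = tibble::tibble(delta = grid, errors = errors,
                                       error_rate = errors / ncol(x)))
}

#' Repeated cross-validated evaluation of a gene signature
#'
#' For each of `repeats` repetitions: a fresh stratified fold assignment
#' (seed + repeat), and for every fold the shrinkage threshold is chosen by
#' [cv_select_delta()] on the training portion alone, an NSC model is fit
#' at that threshold, and the held-out fold is predicted. Test predictions
#' are pooled into one confusion matrix per repeat (positive class = the
#' labels' `positive_group`, i.e. case), from which sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' accuracy `(TP+TN)/n` are computed. Means and sds over repeats summarise
#' the report.
#'
#' @param x Signature-genes x samples matrix (all samples, log scale).
#' @param y Aligned [group_labels()].
#' @param repeats Number of repetitions (default 10).
#' @param folds Folds per repetition (default 10).
#' @param seed Integer root seed.
#' @param n_delta Delta-grid size passed to [cv_select_delta()].
#' @return A `cv_report` list: `per_repeat` tibble (confusion counts,
#'   metrics, median chosen delta per repeat) and `summary` tibble (mean
#'   and sd per metric).
#' @export
evaluate_signature <- function(x, y, repeats = 10, folds = 10, seed = 1,
                               n_delta = 30) {
  if (nrow(x) < 1) stop("empty signature", call. = FALSE)
  g <- y$group[match(colnames(x), y$sample_id)]
  positive <- attr(y, "positive_group") %||% "case"
  negative <- setdiff(c("control", "case"), positive)
  rows <- lapply(seq_len(repeats), function(r) {
    fold <- .stratified_folds(colnames(x), g, folds, seed + r)
    tp <- fp <- tn <- fn <- 0L
    deltas <- numeric(0)
    for (f in sort(unique(fold))) {
      test <- fold == f
      xtr <- x[, !test, drop = FALSE]
      ytr <- y[y$sample_id %in% colnames(xtr), ]
      sel <- cv_select_delta(xtr, ytr, n_delta = n_delta, folds = folds,
                             seed = seed + 97L * r + f)
      model <- fit_nsc(xtr, ytr, delta = sel$delta_star)
      pred <- predict(model, x[, test, drop = FALSE])$class
      truth <- g[test]
      tp <- tp + sum(pred == positive & truth == positive)
      fp <- fp + sum(pred == positive & truth == negative)
      tn <- tn + sum(pred == negative & truth == negative)
      fn <- fn + sum(pred == negative & truth == positive)
      deltas <- c(deltas, sel$delta_star)
    }
    tibble::tibble(
      repeat_id = r, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      accuracy = (tp + tn) / length(g),
      delta_median = median(deltas)
    )
  })
  per_repeat <- dplyr::bind_rows(rows)
  metrics <- c("sensitivity", "specificity", "precision", "accuracy")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_repeat[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) sd(per_repeat[[m]], na.rm = TRUE),
                numeric(1))
  )
  structure(list(per_repeat = per_repeat, summary = summary,
                 repeats = repeats, folds = folds, positive = positive),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d repeats x %d-fold stratified CV (positive = %s)\n",
              x$repeats, x$folds, x$positive))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f (sd %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
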