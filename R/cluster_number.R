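.algos <- c("kmeans", "neuralgas", "single")
.indices <- c("MCA", "Jaccard", "FM", "CQS")

# the 12 objective names, in their fixed column order
.objective_names <- as.vector(t(outer(.algos, .indices, paste, sep = ".")))

# align Q's labels to P's object order; error on mismatched object sets
.align_partitions <- function(p, q) {
  if (length(p$object_ids) != length(q$object_ids) ||
      !setequal(p$object_ids, q$object_ids)) {
    stop("partitions are over different object sets", call. = FALSE)
  }
  q$labels[match(p$object_ids, q$object_ids)]
}

#' Pair counts between two partitions
#'
#' Counts of unordered object pairs co-clustered in both partitions (N11),
#' only the first (N10), only the second (N01), or neither (N00). The four
#' counts sum to `n(n-1)/2`. This is the substrate of the pair-counting
#' agreement indices.
#'
#' @param p,q [partition()] objects over the same object set (matched by
#'   ID, order-independent).
#' @return Named numeric vector `n11`, `n10`, `n01`, `n00`.
#' @export
pair_counts <- function(p, q) {
  ql <- .align_partitions(p, q)
  cpp_pair_counts(p$labels, ql, p$k, q$k)
}

#' Partition-agreement indices: MCA, Jaccard, Fowlkes-Mallows, CQS
#'
#' Four agreement scores in `[0, 1]` between two partitions of the same
#' objects:
#' * `jaccard` = N11 / (N11 + N10 + N01) (0 when the denominator is 0);
#' * `fm` = N11 / sqrt((N11 + N10)(N11 + N01)) (0 when a factor is 0);
#' * `mca` (maximum cluster alignment) = the summed overlap of the
#'   maximum-weight one-to-one matching of clusters on the contingency
#'   table, divided by n;
#' * `cqs` = chance-corrected agreement: the adjusted Rand index mapped
#'   into `[0, 1]` as `(ARI + 1) / 2` (clamped at 0).
#'
#' @inheritParams pair_counts
#' @return Named numeric vector `mca`, `jaccard`, `fm`, `cqs`.
#' @export
agreement_indices <- function(p, q) {
  ql <- .align_partitions(p, q)
  cpp_agreement(p$labels, ql, p$k, q$k)
}

#' Bootstrap stability objective for one (K, algorithm, index) cell
#'
#' Clusters the full data once (the reference partition), then draws `R`
#' bootstrap resamples of the objects; each resample is clustered afresh
#' (replicate seed = `seed + r`) and its partition, restricted to the
#' unique objects drawn (labels taken from the first occurrence of each
#' duplicated object), is compared against the reference restricted to the
#' same objects. The objective is the mean agreement index over replicates:
#' high values mean the clustering at this K is reproducible under
#' resampling.
#'
#' @param x Numeric matrix (objects x features).
#' @param k Number of clusters (>= 2).
#' @param algo `"kmeans"`, `"neuralgas"` or `"single"`.
#' @param index `"MCA"`, `"Jaccard"`, `"FM"` or `"CQS"`.
#' @param R Number of bootstrap replicates (default 50, >= 2).
#' @param seed Integer seed; all resampling and clustering randomness
#'   derives from it.
#' @return The mean index, a number in `[0, 1]`.
#' @export
bootstrap_objective <- function(x, k, algo = .algos, index = .indices,
                                R = 50, seed = 1) {
  algo <- match.arg(algo)
  index <- match.arg(index)
  if (k < 2) stop("bootstrap objectives need K >= 2", call. = FALSE)
  if (R < 2) stop("need R >= 2 bootstrap replicates", call. = FALSE)
  x <- .check_k(x, k)
  idx_name <- c(MCA = "mca", Jaccard = "jaccard", FM = "fm", CQS = "cqs")[index]
  n <- nrow(x)
  ref <- .cluster_with(x, k, algo, seed)
  vals <- numeric(R)
  for (r in seq_len(R)) {
    draw <- NULL
    for (attempt in 0:9) {
      cand <- withr::with_seed(seed + r + attempt * 1000003L,
                               sample.int(n, n, replace = TRUE))
      if (length(unique(cand)) >= k) { draw <- cand; break }
    }
    if (is.null(draw)) {
      stop("could not draw a bootstrap sample with >= K unique objects",
           call. = FALSE)
    }
    xb <- x[draw, , drop = FALSE]
    rownames(xb) <- NULL # duplicated objects must not collide on ID
    pb <- .cluster_with(xb, k, algo, seed + r)
    uniq <- unique(draw)
    rep_labels <- pb$labels[match(uniq, draw)]
    vals[r] <- cpp_agreement(canonicalize_labels(ref$labels[uniq]),
                             canonicalize_labels(rep_labels),
                             length(unique(ref$labels[uniq])),
                             length(unique(rep_labels)))[[idx_name]]
  }
  mean(vals)
}

# deterministic per-cell seed derivation; small and collision-free over the
# grid actually used (K <= ~50, 3 algos, 4 indices)
.cell_seed <- function(seed, k, algo, index) {
  a <- match(algo, .algos)
  i <- match(index, .indices)
  as.integer((seed + 7919L * k + 613L * a + 101L * i) %% .Machine$integer.max)
}

#' Bootstrap stability objectives for a range of candidate cluster numbers
#'
#' Fills the candidate-K x 12-objective score table: the cross product of
#' the three clustering algorithms (k-means, neural gas, single linkage)
#' and the four agreement indices (MCA, Jaccard, FM, CQS), each evaluated
#' by [bootstrap_objective()] with a deterministic per-cell seed derived
#' from `(seed, K, algorithm, index)`.
#'
#' @param x Numeric matrix (objects x features), typically the gene-wise
#'   standardized DEG matrix.
#' @param k_min,k_max Candidate range of cluster numbers; `k_max` defaults
#'   to `min(15, nrow(x) / 10)` (and never below `k_min`).
#' @param R Bootstrap replicates per cell (default 50).
#' @param seed Integer root seed.
#' @return An `objective_matrix` tibble: column `k` plus the 12 objective
#'   columns `kmeans.MCA` ... `single.CQS`, all scores in `[0, 1]`.
#' @export
objective_matrix <- function(x, k_min = 2, k_max = NULL, R = 50, seed = 1) {
  x <- as.matrix(x)
  if (is.null(k_max)) k_max <- max(k_min, min(15, floor(nrow(x) / 10)))
  if (k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  if (k_max > nrow(x) / 2) {
    stop("k_max must be <= half the number of objects", call. = FALSE)
  }
  ks <- k_min:k_max
  scores <- matrix(NA_real_, length(ks), length(.objective_names),
                   dimnames = list(NULL, .objective_names))
  for (ki in seq_along(ks)) {
    for (algo in .algos) {
      for (index in .indices) {
        cell <- paste(algo, index, sep = ".")
        scores[ki, cell] <- bootstrap_objective(
          x, ks[ki], algo, index, R = R,
          seed = .cell_seed(seed, ks[ki], algo, index))
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- dplyr::bind_cols(tibble::tibble(k = ks), out)
  class(out) <- c("objective_matrix", class(out))
  out
}

# strict-win counts: for each row i and j, on how many objectives row i
# strictly beats row j
.win_counts <- function(scores) {
  n <- nrow(scores)
  w <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w[i, j] <- sum(scores[i, ] > scores[j, ])
    }
  }
  w
}

#' Pareto ranking of candidate cluster numbers
#'
#' Maximizing all 12 objectives: a candidate K is Pareto-optimal
#' (non-dominated) if no other candidate is at least as good on every
#' objective and strictly better on at least one. Pareto-optimal candidates
#' are ranked by their total dominance count — the summed number of
#' objectives on which they strictly beat each other candidate — in
#' descending order, ties broken by smaller K. The full dominance-count
#' matrix is returned so alternative orderings can be recomputed.
#'
#' @param m An [objective_matrix()] tibble (column `k` + objective columns).
#' @param tie_break Only `"smallest_k"` is implemented.
#' @return A `pareto_result` list: `pareto_k` (ranked non-dominated K),
#'   `dominance_counts` (Pareto K x all candidates matrix of strict-win
#'   counts), `rank_key` (total dominance per Pareto K) and `selected_k`.
#' @export
pareto_rank <- function(m, tie_break = "smallest_k") {
  stopifnot(tie_break == "smallest_k")
  ks <- m$k
  scores <- as.matrix(m[, setdiff(names(m), "k"), drop = FALSE])
  if (any(!is.finite(scores))) stop("objective scores must be finite",
                                    call. = FALSE)
  n <- nrow(scores)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && all(scores[j, ] >= scores[i, ]) && any(scores[j, ] > scores[i, ])
    }, logical(1)))
  }, logical(1))
  pareto_idx <- which(!dominated)
  w <- .win_counts(scores)
  dom <- w[pareto_idx, , drop = FALSE]
  rownames(dom) <- ks[pareto_idx]
  colnames(dom) <- ks
  rank_key <- rowSums(dom)
  ord <- order(-rank_key, ks[pareto_idx])
  res <- structure(list(
    pareto_k = ks[pareto_idx][ord],
    dominance_counts = dom[ord, , drop = FALSE],
    rank_key = rank_key[ord],
    selected_k = ks[pareto_idx][ord][1],
    k_values = ks
  ), class = "pareto_result")
  res
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("<pareto_result> selected K = %d; Pareto-optimal K: %s\n",
              x$selected_k, paste(x$pareto_k, collapse = ", ")))
  cat("total dominance:", paste(sprintf("%d (K=%d)", x$rank_key, x$pareto_k),
                                collapse = ", "), "\n")
  invisible(x)
}
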