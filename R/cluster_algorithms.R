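#' Partition object
#'
#' A labelled clustering of objects (genes). Labels are canonicalized:
#' clusters are renumbered in first-occurrence order so two partitions that
#' differ only by a label permutation compare equal after canonicalization.
#'
#' @param object_ids Character vector of object identifiers.
#' @param labels Integer cluster labels, one per object, each cluster in
#'   `1..k` non-empty.
#' @return A `partition` object (list with `object_ids`, `labels`, `k`).
#' @export
partition <- function(object_ids, labels) {
  labels <- canonicalize_labels(labels)
  if (length(object_ids) != length(labels)) {
    stop("object_ids and labels differ in length", call. = FALSE)
  }
  structure(list(object_ids = as.character(object_ids),
                 labels = labels, k = max(labels)),
            class = "partition")
}

#' Renumber cluster labels by first occurrence
#' @param labels Integer (or factor-like) cluster labels.
#' @return Integer labels in 1..K, first occurrence order.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d objects in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.partition <- function(x, ...) {
  data.frame(gene_id = x$object_ids, cluster = x$labels,
             stringsAsFactors = FALSE)
}

#' Coerce a partition to a tibble
#' @param x A `partition`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `cluster`.
#' @export
as_tibble.partition <- function(x, ...) {
  tibble::tibble(gene_id = x$object_ids, cluster = x$labels)
}

.check_k <- function(x, k) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (k > nrow(x)) {
    stop("K (", k, ") exceeds the number of objects (", nrow(x), ")",
         call. = FALSE)
  }
  if (k < 1) stop("K must be >= 1", call. = FALSE)
  x
}

.obj_ids <- function(x) {
  if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
}

#' K-means clustering (k-means++ seeding, Lloyd iterations)
#'
#' Best of `n_init` restarts by within-cluster sum of squares; empty
#' clusters are repaired by reseeding them with the point farthest from its
#' centroid. Deterministic given `seed` (the seed drives a private RNG, so
#' R's global RNG state is untouched).
#'
#' @param x Numeric matrix, objects (genes) in rows, features (samples) in
#'   columns.
#' @param k Number of clusters (`1 <= k <= nrow(x)`).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative WCSS improvement below which iteration stops.
#' @return A [partition()]; the winning WCSS is attached as attribute
#'   `wcss`.
#' @export
cluster_kmeans <- function(x, k, seed = 1, n_init = 10, max_iter = 300,
                           tol = 1e-6) {
  x <- .check_k(x, k)
  res <- cpp_kmeans(x, k, as.integer(seed), n_init, max_iter, tol)
  p <- partition(.obj_ids(x), res$labels)
  attr(p, "wcss") <- res$wcss
  p
}

#' Neural gas clustering
#'
#' Online Martinetz-Schulten neural gas: prototypes are initialized from K
#' distinct data points and, for every presented sample, all prototypes move
#' toward it with strength `eps(t) * exp(-rank / lambda(t))`, where rank is
#' the prototype's distance rank for that sample and both `eps` and
#' `lambda` decay exponentially from their initial to final values over
#' `epochs * n` presentations. The returned partition assigns each object
#' to its nearest final prototype (the K x S codebook is attached as the
#' `prototypes` attribute). Deterministic given `seed`.
#'
#' @inheritParams cluster_kmeans
#' @param epochs Passes through the data (default 100).
#' @param lambda0 Initial neighbourhood range; default `k / 2`.
#' @param lambda_final Final neighbourhood range (default 0.01).
#' @param eps0 Initial learning rate (default 0.5).
#' @param eps_final Final learning rate (default 0.005).
#' @return A [partition()].
#' @export
cluster_neural_gas <- function(x, k, seed = 1, epochs = 100,
                               lambda0 = NULL, lambda_final = 0.01,
                               eps0 = 0.5, eps_final = 0.005) {
  x <- .check_k(x, k)
  if (is.null(lambda0)) lambda0 <- k / 2
  res <- cpp_neural_gas(x, k, as.integer(seed), epochs, lambda0,
                        lambda_final, eps0, eps_final)
  p <- partition(.obj_ids(x), res$labels)
  attr(p, "prototypes") <- res$prototypes
  p
}

#' Single-linkage hierarchical clustering cut at K clusters
#'
#' Agglomerative single-linkage on Euclidean distances (via
#' [stats::hclust()]), dendrogram cut to exactly `k` clusters.
#' Deterministic.
#'
#' @inheritParams cluster_kmeans
#' @return A [partition()].
#' @export
cluster_single <- function(x, k) {
  x <- .check_k(x, k)
  hc <- hclust(dist(x, method = "euclidean"), method = "single")
  partition(.obj_ids(x), cutree(hc, k = k))
}

# dispatch used by the bootstrap stage; seed is ignored where irrelevant
.cluster_with <- function(x, k, algo, seed) {
  switch(algo,
         kmeans = cluster_kmeans(x, k, seed = seed),
         neuralgas = cluster_neural_gas(x, k, seed = seed),
         single = cluster_single(x, k),
         stop("unknown clustering algorithm: ", algo, call. = FALSE))
}
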