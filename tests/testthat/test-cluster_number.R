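test_that("pair counts match hand-enumerated and brute-force values", {
  p <- partition(c("a", "b", "c"), c(1, 1, 2))
  expect_equal(pair_counts(p, p), c(n11 = 1, n10 = 0, n01 = 0, n00 = 2))
  p1 <- partition(c("a", "b", "c"), c(1, 1, 1))
  q1 <- partition(c("a", "b", "c"), c(1, 2, 3))
  expect_equal(pair_counts(p1, q1), c(n11 = 0, n10 = 3, n01 = 0, n00 = 0))
  p2 <- partition(as.character(1:4), c(1, 1, 2, 2))
  q2 <- partition(as.character(1:4), c(1, 1, 1, 2))
  expect_equal(pair_counts(p2, q2), c(n11 = 1, n10 = 1, n01 = 2, n00 = 2))
  # order-independent: q given in shuffled object order
  q3 <- partition(c("3", "1", "4", "2"), c(1, 2, 3, 2))
  expect_equal(pair_counts(p2, q3),
               oracle_pair_counts(c(1, 1, 2, 2), c(2, 2, 1, 3)),
               ignore_attr = TRUE)
  expect_error(pair_counts(p2, partition(c("x", "y", "z", "w"), c(1, 1, 2, 2))),
               "different object sets")
})

test_that("agreement indices equal identity, worked example and chance-corrected score", {
  p <- partition(as.character(1:4), c(1, 1, 2, 2))
  expect_equal(agreement_indices(p, p),
               c(mca = 1, jaccard = 1, fm = 1, cqs = 1))
  q <- partition(as.character(1:4), c(1, 1, 1, 2))
  ai <- agreement_indices(p, q)
  expect_equal(ai[["jaccard"]], 0.25)
  expect_equal(ai[["fm"]], 1 / sqrt(6))
  expect_equal(ai[["mca"]], 0.75)
  skip_if_not_installed("mclust")
  # cqs = (ARI + 1) / 2 against the mclust reference, over random pairs
  withr::with_seed(31, {
    for (i in 1:25) {
      la <- sample(1:3, 12, replace = TRUE)
      lb <- sample(1:3, 12, replace = TRUE)
      pp <- partition(as.character(1:12), la)
      qq <- partition(as.character(1:12), lb)
      ari <- mclust::adjustedRandIndex(la, lb)
      expect_equal(agreement_indices(pp, qq)[["cqs"]],
                   max((ari + 1) / 2, 0), tolerance = 1e-12)
    }
  })
})

test_that("indices equal the exhaustive brute-force oracle on small partitions", {
  # all partition pairs of 5 objects into <= 3 clusters, exact equality
  parts <- enum_partitions(5, 3)
  ids <- as.character(1:5)
  for (i in seq_len(nrow(parts))) {
    for (j in seq_len(nrow(parts))) {
      ai <- agreement_indices(partition(ids, parts[i, ]),
                              partition(ids, parts[j, ]))
      or <- oracle_indices(parts[i, ], parts[j, ])
      expect_equal(ai[["jaccard"]], or[["jaccard"]])
      expect_equal(ai[["fm"]], or[["fm"]])
      expect_equal(ai[["mca"]], or[["mca"]])
    }
  }
})

test_that("mca is 1 exactly for relabelings and below 1 otherwise", {
  skip_if_not_installed("igraph")
  withr::with_seed(17, {
    for (i in 1:30) {
      la <- canonicalize_labels(sample(1:4, 15, replace = TRUE))
      relab <- canonicalize_labels(max(la) + 1 - la) # reversed labels
      ids <- as.character(1:15)
      expect_equal(agreement_indices(partition(ids, la),
                                     partition(ids, relab))[["mca"]], 1)
      lb <- canonicalize_labels(sample(1:4, 15, replace = TRUE))
      mca <- agreement_indices(partition(ids, la),
                               partition(ids, lb))[["mca"]]
      # mca = 1 iff identical up to relabeling, i.e. canonical forms match
      expect_identical(mca == 1, identical(la, lb))
      # independent weighted-matching oracle via igraph
      ka <- max(la); kb <- max(lb)
      cont <- table(factor(la, 1:ka), factor(lb, 1:kb))
      g <- igraph::make_bipartite_graph(
        rep(c(FALSE, TRUE), c(ka, kb)),
        as.vector(t(cbind(rep(1:ka, each = kb), ka + rep(1:kb, ka)))))
      w <- as.vector(t(cont)) + 1e-9 # strictly positive weights
      mm <- igraph::max_bipartite_match(g, weights = w)
      expect_equal(mca, (mm$matching_weight - min(ka, kb) * 1e-9) / 15,
                   tolerance = 1e-9)
    }
  })
})

test_that("bootstrap stability is near 1 on separated blobs and degrades on noise", {
  X <- two_blobs()
  for (s in 0:4) {
    for (idx in c("MCA", "Jaccard", "FM")) {
      expect_gte(bootstrap_objective(X, 2, "kmeans", idx, R = 20, seed = s),
                 0.95)
    }
  }
  # unstructured data: overfit K is strictly less stable (5-seed average)
  j2 <- j6 <- numeric(5)
  for (s in 1:5) {
    withr::with_seed(s, Xn <- matrix(rnorm(60 * 5), 60))
    rownames(Xn) <- paste0("g", 1:60)
    j2[s] <- bootstrap_objective(Xn, 2, "kmeans", "Jaccard", R = 20, seed = s)
    j6[s] <- bootstrap_objective(Xn, 6, "kmeans", "Jaccard", R = 20, seed = s)
  }
  expect_lt(mean(j6), mean(j2))
  # duplicated rows: objective still well-defined
  Xd <- two_blobs(n_per = 3)[rep(1:6, 2), ]
  rownames(Xd) <- paste0("g", 1:12)
  v <- bootstrap_objective(Xd, 2, "single", "Jaccard", R = 2, seed = 1)
  expect_true(is.finite(v) && v >= 0 && v <= 1)
})

test_that("objective matrix has the canonical 12 columns and is deterministic", {
  X <- two_blobs(n_per = 10, S = 3)
  m1 <- objective_matrix(X, k_min = 2, k_max = 4, R = 5, seed = 9)
  expect_identical(
    names(m1),
    c("k", "kmeans.MCA", "kmeans.Jaccard", "kmeans.FM", "kmeans.CQS",
      "neuralgas.MCA", "neuralgas.Jaccard", "neuralgas.FM", "neuralgas.CQS",
      "single.MCA", "single.Jaccard", "single.FM", "single.CQS"))
  expect_true(all(as.matrix(m1[, -1]) >= 0 & as.matrix(m1[, -1]) <= 1))
  m2 <- objective_matrix(X, k_min = 2, k_max = 4, R = 5, seed = 9)
  expect_identical(m1, m2)
  expect_error(objective_matrix(X, k_min = 2, k_max = 11, R = 5, seed = 1),
               "half")
})

test_that("pareto ranking follows dominance with declared tie-breaks", {
  m <- tibble::tibble(k = 2:4, o1 = c(0.9, 0.1, 0.5), o2 = c(0.1, 0.9, 0.5))
  pr <- pareto_rank(m)
  expect_setequal(pr$pareto_k, 2:4) # all non-dominated
  # single dominating row
  m2 <- tibble::tibble(k = 2:4, o1 = c(0.5, 0.9, 0.5), o2 = c(0.5, 0.9, 0.4))
  pr2 <- pareto_rank(m2)
  expect_identical(pr2$pareto_k, 3L)
  expect_identical(pr2$selected_k, 3L)
  # identical rows: every K Pareto-optimal, zero dominance, smallest K wins
  m3 <- tibble::tibble(k = c(5L, 2L, 9L), o1 = rep(0.4, 3), o2 = rep(0.4, 3))
  pr3 <- pareto_rank(m3)
  expect_setequal(pr3$pareto_k, c(2L, 5L, 9L))
  expect_true(all(pr3$rank_key == 0))
  expect_identical(pr3$selected_k, 2L)
})

test_that("pareto ranking is invariant under candidate-row permutation", {
  withr::with_seed(13, {
    sc <- matrix(runif(8 * 12), 8)
    colnames(sc) <- paste0("o", 1:12)
    m <- dplyr::bind_cols(tibble::tibble(k = 2:9),
                          tibble::as_tibble(as.data.frame(sc)))
    pr <- pareto_rank(m)
    mp <- m[sample(8), ]
    prp <- pareto_rank(mp)
    expect_identical(pr$selected_k, prp$selected_k)
    expect_setequal(pr$pareto_k, prp$pareto_k)
    expect_equal(pr$rank_key[order(pr$pareto_k)],
                 prp$rank_key[order(prp$pareto_k)], ignore_attr = TRUE)
  })
})
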