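test_that("spearman correlation handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  # ties: equals brute-force mid-rank Pearson
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  brute <- cor(rank(x, ties.method = "average"),
               rank(y, ties.method = "average"))
  expect_equal(spearman_rho(x, y), brute)
  expect_true(is.na(spearman_rho(c(2, 2, 2), 1:3)))
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("module scores equal brute-force pairwise averages; singletons are NA", {
  withr::with_seed(8, X <- matrix(rnorm(5 * 12), 5))
  dimnames(X) <- list(paste0("g", 1:5), paste0("s", 1:12))
  p <- partition(rownames(X), c(1, 1, 1, 2, 3))
  sc <- score_modules(X, p)
  # 3-gene cluster: mean of the 3 pairwise rhos
  rhos <- c(spearman_rho(X[1, ], X[2, ]), spearman_rho(X[1, ], X[3, ]),
            spearman_rho(X[2, ], X[3, ]))
  expect_equal(sc$avg_spearman[1], mean(rhos))
  expect_true(is.na(sc$avg_spearman[2])) # singleton clusters are unscorable
  expect_true(is.na(sc$avg_spearman[3]))
  expect_equal(sc$n_genes, c(3L, 1L, 1L))
  # two genes with identical sample rankings
  X2 <- rbind(g1 = 1:6, g2 = c(2, 4, 6, 8, 10, 12))
  colnames(X2) <- paste0("s", 1:6)
  p2 <- partition(c("g1", "g2"), c(1, 1))
  expect_equal(score_modules(X2, p2)$avg_spearman, 1)
})

test_that("module scores tally DE status and exclude undefined pairs", {
  X <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 3, 4, 5), g3 = c(7, 7, 7, 7))
  colnames(X) <- paste0("s", 1:4)
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       status = c("up", "down", "up"))
  p <- partition(rownames(X), c(1, 1, 1))
  sc <- score_modules(X, p, de)
  expect_equal(sc$n_up, 2L)
  expect_equal(sc$n_down, 1L)
  # g3 is constant: its two pairs are excluded, leaving rho(g1, g2) = 1
  expect_equal(sc$n_pairs_excluded, 2L)
  expect_equal(sc$avg_spearman, 1)
})

test_that("best-module selection maximizes the score with declared tie-breaks", {
  # the five-module score profile: the fourth, highest-scoring module wins
  scores <- tibble::tibble(
    cluster_id = 1:5, n_genes = c(113L, 213L, 95L, 35L, 126L),
    n_up = NA_integer_, n_down = NA_integer_, n_pairs_excluded = 0L,
    avg_spearman = c(0.312, 0.201, 0.309, 0.521, 0.211))
  p <- partition(paste0("g", 1:582),
                 rep(1:5, c(113, 213, 95, 35, 126)))
  sig <- pick_signature(scores, p)
  expect_identical(sig$source_cluster, 4L)
  expect_equal(sig$score, 0.521)
  expect_equal(length(sig$gene_ids), 35)
  # tie on score: larger module wins
  tie <- tibble::tibble(cluster_id = 1:2, n_genes = c(3L, 10L),
                        n_up = NA_integer_, n_down = NA_integer_,
                        n_pairs_excluded = 0L, avg_spearman = c(0.5, 0.5))
  pt <- partition(paste0("g", 1:13), rep(1:2, c(3, 10)))
  expect_identical(pick_signature(tie, pt)$source_cluster, 2L)
  # all-singleton scores are an error
  single <- tibble::tibble(cluster_id = 1L, n_genes = 1L, n_up = NA_integer_,
                           n_down = NA_integer_, n_pairs_excluded = 0L,
                           avg_spearman = NA_real_)
  ps <- partition("g1", 1)
  expect_error(pick_signature(single, ps), "no scorable")
})

test_that("module scores are invariant under monotone per-gene transforms", {
  withr::with_seed(23, X <- matrix(rnorm(6 * 15), 6))
  dimnames(X) <- list(paste0("g", 1:6), paste0("s", 1:15))
  p <- partition(rownames(X), c(1, 1, 1, 2, 2, 2))
  sc1 <- score_modules(X, p)
  Xt <- X
  Xt[1, ] <- exp(X[1, ])          # strictly increasing
  Xt[2, ] <- X[2, ]^3             # strictly increasing
  Xt[4, ] <- 5 * X[4, ] + 2       # affine
  sc2 <- score_modules(Xt, p)
  expect_equal(sc1$avg_spearman, sc2$avg_spearman, tolerance = 1e-12)
})

test_that("a planted high-correlation module is recovered as the signature", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_expression(
      n_genes = 100, n_control = 30, n_case = 30, n_modules = 5,
      genes_per_module = 20, within_module_rho = c(0.2, 0.2, 0.8, 0.2, 0.2),
      de_fraction = 0, log2_effect = 0, noise_sd = 1,
      count_model = "gaussian_log", seed = 300 + s)
    Z <- standardize_genes(sim$expression)
    p <- cluster_kmeans(Z, 5, seed = s)
    sig <- pick_signature(score_modules(Z, p), p)
    planted <- planted_module_genes(sim$truth, 3)
    if (set_jaccard(sig$gene_ids, planted) == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
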