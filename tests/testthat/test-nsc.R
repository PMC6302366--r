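# small two-class fixture with a controllable separation
nsc_fixture <- function(n_genes = 10, n1 = 10, n2 = 10, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_genes * (n1 + n2)), n_genes)
    X[, (n1 + 1):(n1 + n2)] <- X[, (n1 + 1):(n1 + n2)] + sep
  })
  dimnames(X) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n1 + n2)))
  list(x = X, y = group_labels(colnames(X),
                               rep(c("control", "case"), c(n1, n2))))
}

test_that("the one-gene worked example reproduces the shrinkage formulas", {
  X <- matrix(c(1, 3, 5, 7), 1, dimnames = list("g1", paste0("s", 1:4)))
  y <- group_labels(colnames(X), c("control", "control", "case", "case"))
  m <- fit_nsc(X, y, delta = 1)
  expect_equal(m$overall[["g1"]], 4)
  expect_equal(m$s[["g1"]], sqrt(2), tolerance = 1e-12)
  expect_equal(unname(m$mk), c(0.5, 0.5))
  expect_equal(m$s0, sqrt(2))
  expect_equal(m$d["g1", "control"], -sqrt(2), tolerance = 1e-12)
  expect_equal(m$d_shrunk["g1", "control"], -(sqrt(2) - 1), tolerance = 1e-12)
  expect_equal(m$shrunken_centroids["g1", "control"],
               4 - sqrt(2) * (sqrt(2) - 1), tolerance = 1e-9)
})

test_that("delta limits: 0 leaves centroids untouched, full shrinkage erases them", {
  fx <- nsc_fixture(sep = 1, seed = 2)
  m0 <- fit_nsc(fx$x, fx$y, delta = 0)
  expect_equal(m0$shrunken_centroids, m0$centroids, tolerance = 1e-12)
  dmax <- max(abs(m0$d))
  mfull <- fit_nsc(fx$x, fx$y, delta = dmax + 0.1)
  expect_true(all(mfull$d_shrunk == 0))
  expect_equal(mfull$shrunken_centroids[, "control"], mfull$overall)
  expect_equal(mfull$shrunken_centroids[, "case"], mfull$overall)
})

test_that("shrinkage zeroes a non-increasing set of genes as delta grows", {
  fx <- nsc_fixture(n_genes = 40, sep = 0.5, seed = 3)
  m0 <- fit_nsc(fx$x, fx$y, 0)
  deltas <- seq(0, max(abs(m0$d)) * 1.05, length.out = 25)
  active <- vapply(deltas, function(d) {
    sum(rowSums(fit_nsc(fx$x, fx$y, d)$d_shrunk != 0) > 0)
  }, numeric(1))
  expect_true(all(diff(active) <= 0))
  expect_equal(active[1], 40)
  expect_equal(active[length(active)], 0)
})

test_that("predictions follow the discriminant with control on ties", {
  fx <- nsc_fixture(sep = 3, seed = 4)
  m <- fit_nsc(fx$x, fx$y, delta = 0)
  # a sample equal to a shrunken centroid maps to that class (equal priors)
  expect_identical(predict(m, m$shrunken_centroids[, "case"])$class, "case")
  expect_identical(predict(m, m$shrunken_centroids[, "control"])$class,
                   "control")
  # separable data at delta 0: perfect training accuracy
  pred <- predict(m, fx$x)
  expect_identical(pred$class,
                   rep(c("control", "case"), each = 10))
  # fully shrunken model predicts the larger-prior class everywhere
  fx2 <- nsc_fixture(n1 = 6, n2 = 14, sep = 2, seed = 5)
  m2 <- fit_nsc(fx2$x, fx2$y, delta = max(abs(fit_nsc(fx2$x, fx2$y, 0)$d)) + 1)
  expect_true(all(predict(m2, fx2$x)$class == "case"))
  expect_error(predict(m, fx$x[1:3, ]), "genes")
})

test_that("delta = 0 equals plain standardized nearest-centroid classification", {
  for (s in 1:20) {
    fx <- nsc_fixture(n_genes = 8, n1 = 9, n2 = 9, sep = 0.8, seed = 100 + s)
    m <- fit_nsc(fx$x, fx$y, delta = 0)
    pred <- predict(m, fx$x)$class
    # independent nearest-centroid computation (balanced classes, so the
    # prior term cancels)
    cen_c <- rowMeans(fx$x[, 1:9])
    cen_k <- rowMeans(fx$x[, 10:18])
    ssq <- (rowSums((fx$x[, 1:9] - cen_c)^2) +
              rowSums((fx$x[, 10:18] - cen_k)^2)) / (18 - 2)
    s0 <- median(sqrt(ssq))
    denom <- (sqrt(ssq) + s0)^2
    ref <- apply(fx$x, 2, function(v) {
      if (sum((v - cen_k)^2 / denom) < sum((v - cen_c)^2 / denom)) "case"
      else "control"
    })
    expect_identical(pred, unname(ref))
  }
})

test_that("cross-validated delta selection is deterministic and parsimonious", {
  fx <- nsc_fixture(n_genes = 15, n1 = 12, n2 = 24, sep = 3, seed = 6)
  sel1 <- cv_select_delta(fx$x, fx$y, folds = 6, seed = 11)
  sel2 <- cv_select_delta(fx$x, fx$y, folds = 6, seed = 11)
  expect_identical(sel1, sel2)
  # separable data: zero CV error attained, and shrinkage is preferred at
  # equal error (largest delta at the minimum)
  expect_equal(min(sel1$cv_error_curve$errors), 0)
  expect_gt(sel1$delta_star, 0)
  # a grid of length 1 returns its only delta (0)
  sel3 <- cv_select_delta(fx$x, fx$y, n_delta = 1, folds = 6, seed = 1)
  expect_equal(sel3$delta_star, 0)
})

test_that("repeated CV reports are invariant to sample order", {
  fx <- nsc_fixture(n_genes = 10, n1 = 10, n2 = 20, sep = 2, seed = 7)
  r1 <- evaluate_signature(fx$x, fx$y, repeats = 2, folds = 5, seed = 3,
                           n_delta = 8)
  perm <- withr::with_seed(1, sample(30))
  r2 <- evaluate_signature(fx$x[, perm], fx$y, repeats = 2, folds = 5,
                           seed = 3, n_delta = 8)
  expect_equal(r1$per_repeat, r2$per_repeat)
  expect_equal(r1$summary, r2$summary)
})

test_that("a permuted-label null signature scores near the majority frequency", {
  fx <- nsc_fixture(n_genes = 12, n1 = 15, n2 = 25, sep = 2, seed = 8)
  ynull <- withr::with_seed(2, group_labels(fx$y$sample_id,
                                            sample(fx$y$group)))
  r <- evaluate_signature(fx$x, ynull, repeats = 10, folds = 5, seed = 5,
                          n_delta = 10)
  maj <- max(table(ynull$group)) / nrow(ynull)
  acc <- r$summary$mean[r$summary$metric == "accuracy"]
  expect_lt(abs(acc - maj), 0.1)
})
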