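test_that("two-group fit gives exact means, fold changes and variances", {
  Y <- rbind(g1 = c(1, 1, 3, 3), g2 = c(2, 2, 2, 2), g3 = c(0, 2, 5, 9))
  colnames(Y) <- paste0("s", 1:4)
  attr(Y, "value_scale") <- "other"
  gl <- group_labels(colnames(Y), c("control", "control", "case", "case"))
  fit <- fit_two_group(Y, gl)
  expect_equal(fit$log2fc, c(2, 0, 6))
  expect_equal(fit$s2, c(0, 0, (2 + 8) / 2))
  expect_equal(fit$df_residual, rep(2L, 3), ignore_attr = TRUE)
  expect_equal(fit$v, rep(1, 3))
  # unit weights reproduce the unweighted fit exactly
  fitw <- fit_two_group(Y, gl, weights = matrix(1, 3, 4))
  expect_equal(fitw, fit)
  expect_error(fit_two_group(Y[, 1:3],
                             group_labels(paste0("s", 1:3),
                                          c("control", "control", "case"))),
               ">= 2 samples")
})

test_that("variance shrinkage interpolates between data and prior", {
  # limit cases and the closed-form example
  expect_equal(shrink_var(3, df = 4, d0 = 4, s0_sq = 1), 2)
  expect_equal(shrink_var(c(1, 5), df = 4, d0 = Inf, s0_sq = 2), c(2, 2))
  expect_equal(shrink_var(c(1, 5), df = 4, d0 = 0, s0_sq = 2), c(1, 5))

  withr::with_seed(7, s2 <- rchisq(500, df = 6) / 6)
  eb <- ebayes_moderate(s2, df = 6)
  expect_true(eb$d0 > 0 && eb$s0_sq > 0)
  lo <- pmin(s2, eb$s0_sq)
  hi <- pmax(s2, eb$s0_sq)
  expect_true(all(eb$s2_tilde >= lo - 1e-12 & eb$s2_tilde <= hi + 1e-12))
  expect_true(all(eb$s2_tilde > 0))
  # identical variances: the infinite-d0 branch, not an error
  eb2 <- ebayes_moderate(rep(2, 50), df = 4)
  expect_equal(eb2$s2_tilde, rep(eb2$s0_sq, 50))
})

test_that("moderated test agrees with the limma reference pipeline", {
  fx <- gaussian_expression(n_genes = 300, n1 = 6, n2 = 10, seed = 3,
                            effect_genes = 1:30, effect = 1.2)
  de <- moderated_de(fx$y, fx$groups)
  design <- cbind(1, fx$groups$group == "case")
  lf <- limma::eBayes(limma::lmFit(fx$y, design))
  expect_equal(de$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(de$t_mod, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(attr(de, "d0"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_sq"), lf$s2.prior, tolerance = 1e-6)
  # p-values agree up to limma's finite cap on the total degrees of freedom
  # (limma truncates df.total at the pooled residual df; we use d0 + df)
  expect_equal(de$p, unname(lf$p.value[, 2]), tolerance = 0.02)
  expect_equal(de$p, unname(2 * pt(-abs(lf$t[, 2]), attr(de, "d0") + 14)),
               tolerance = 1e-10)
})

test_that("volcano bi-filter partitions genes by p and fold change", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    p = c(0.01, 0.2, 0.01, 0.04),
    fold_change = c(4, 4, 0.4, 1.2),
    status = c("up", "ns", "down", "ns")
  )
  vf <- volcano_filter(de)
  expect_identical(vf$up, "a")
  expect_identical(vf$down, "c")
  # real DE table: up/down/ns partition the gene set
  fx <- gaussian_expression(n_genes = 400, n1 = 8, n2 = 8, seed = 9,
                            effect_genes = 1:40, effect = 1.5)
  full <- moderated_de(fx$y, fx$groups)
  expect_setequal(unique(full$status), c("up", "down", "ns")[
    c("up", "down", "ns") %in% full$status])
  expect_equal(sum(full$status == "up") + sum(full$status == "down") +
                 sum(full$status == "ns"), nrow(full))
  vf2 <- volcano_filter(full)
  expect_identical(vf2$up, full$gene_id[full$status == "up"])
})

test_that("swapping group labels negates effects and swaps up/down", {
  fx <- gaussian_expression(n_genes = 300, n1 = 7, n2 = 9, seed = 5,
                            effect_genes = 1:40, effect = 1.5)
  de1 <- moderated_de(fx$y, fx$groups)
  swapped <- group_labels(fx$groups$sample_id,
                          ifelse(fx$groups$group == "case", "control", "case"))
  de2 <- moderated_de(fx$y, swapped)
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$p, de1$p, tolerance = 1e-12)
  expect_identical(volcano_filter(de2)$up, volcano_filter(de1)$down)
  expect_identical(volcano_filter(de2)$down, volcano_filter(de1)$up)
})
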