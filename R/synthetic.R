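#' Simulate two-group expression data with planted DE genes and modules
#'
#' Generates a genes x samples dataset with the structure every pipeline
#' stage assumes: two (typically unbalanced) sample groups, a set of
#' differentially expressed genes, and correlated gene modules of known
#' number and membership. Module co-expression uses a single latent factor
#' per module: for member gene g of module m in sample s, the log2
#' expression is
#' `baseline_g + noise_sd * (sqrt(rho) * f_ms + sqrt(1 - rho) * eps_gs)`,
#' plus `log2_effect` in case samples for DE genes; the expected pairwise
#' within-module correlation on the Gaussian scale is exactly `rho`.
#' Background genes are independent noise. Under
#' `count_model = "lognormal_counts"` the log2 values are exponentiated and
#' Poisson-rounded into non-negative integer counts; `"gaussian_log"`
#' returns the log2 values directly.
#'
#' Everything is deterministic given `seed`.
#'
#' @param n_genes Total genes.
#' @param n_control,n_case Samples per group.
#' @param n_modules Number of planted modules (K*).
#' @param genes_per_module Genes per module (recycled to `n_modules`);
#'   `sum <= n_genes`.
#' @param within_module_rho Within-module correlation in `[0, 1)`, scalar
#'   or one value per module.
#' @param de_fraction Fraction of each module's genes that are DE, scalar
#'   or per module.
#' @param log2_effect Case-minus-control log2 effect for DE genes, scalar
#'   or per module; the sign sets the direction (up/down).
#' @param noise_sd Per-gene log2 noise sd (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression is
#'   drawn from N(baseline_mean, baseline_sd) (defaults 6 and 1.5).
#' @param count_model `"lognormal_counts"` or `"gaussian_log"`.
#' @param seed Integer seed.
#' @return A list: `expression` (expression matrix; counts or log2 values),
#'   `groups` ([group_labels()]), and `truth` — a list with `module`
#'   tibble (`gene_id`, `module` with 0 = background, `de_status`) and
#'   `k_star`.
#' @export
simulate_expression <- function(n_genes = 2000, n_control = 22, n_case = 253,
                                n_modules = 5, genes_per_module = 40,
                                within_module_rho = 0.3, de_fraction = 1,
                                log2_effect = 1.5, noise_sd = 1,
                                baseline_mean = 6, baseline_sd = 1.5,
                                count_model = c("lognormal_counts", "gaussian_log"),
                                seed = 1) {
  count_model <- match.arg(count_model)
  gpm <- rep_len(genes_per_module, n_modules)
  rho <- rep_len(within_module_rho, n_modules)
  frac <- rep_len(de_fraction, n_modules)
  eff <- rep_len(log2_effect, n_modules)
  if (sum(gpm) > n_genes) {
    stop("module genes (", sum(gpm), ") exceed n_genes (", n_genes, ")",
         call. = FALSE)
  }
  if (any(rho < 0 | rho >= 1)) stop("within_module_rho must be in [0, 1)",
                                    call. = FALSE)
  if (n_control < 1 || n_case < 1 || n_genes < 1 || n_modules < 0) {
    stop("counts must be >= 1", call. = FALSE)
  }
  S <- n_control + n_case
  sample_ids <- c(sprintf("CTRL_%03d", seq_len(n_control)),
                  sprintf("CASE_%03d", seq_len(n_case)))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  is_case <- rep(c(0, 1), c(n_control, n_case))

  module <- integer(n_genes)
  pos <- 1L
  for (m in seq_len(n_modules)) {
    module[pos:(pos + gpm[m] - 1L)] <- m
    pos <- pos + gpm[m]
  }
  de_status <- rep("ns", n_genes)

  logexpr <- withr::with_seed(seed, {
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    f <- matrix(rnorm(n_modules * S), n_modules, S) # latent factor per module
    eps <- matrix(rnorm(n_genes * S), n_genes, S)
    z <- eps
    for (m in seq_len(n_modules)) {
      idx <- which(module == m)
      z[idx, ] <- sqrt(rho[m]) * matrix(f[m, ], length(idx), S, byrow = TRUE) +
        sqrt(1 - rho[m]) * eps[idx, ]
      n_de <- round(frac[m] * length(idx))
      if (n_de > 0) {
        de_idx <- idx[seq_len(n_de)]
        de_status[de_idx] <- if (eff[m] >= 0) "up" else "down"
      }
    }
    le <- baseline + noise_sd * z
    de <- which(de_status != "ns")
    if (length(de) > 0) {
      shift <- eff[module[de]]
      le[de, ] <- le[de, ] + outer(shift, is_case)
    }
    le
  })
  dimnames(logexpr) <- list(gene_ids, sample_ids)

  if (count_model == "lognormal_counts") {
    counts <- withr::with_seed(seed + 1L, {
      matrix(rpois(length(logexpr), lambda = 2^logexpr),
             nrow(logexpr), dimnames = dimnames(logexpr))
    })
    expr <- expression_matrix(counts * 1.0, "counts")
  } else {
    expr <- expression_matrix(logexpr, "other")
  }
  groups <- group_labels(sample_ids,
                         rep(c("control", "case"), c(n_control, n_case)))
  truth <- list(
    module = tibble::tibble(gene_id = gene_ids, module = module,
                            de_status = de_status),
    k_star = n_modules
  )
  list(expression = expr, groups = groups, truth = truth)
}

#' Convenience preset echoing a TCGA-like two-subtype design
#'
#' 2,000 genes over 22 control + 253 case samples with K* = 5 planted
#' modules of 40 genes each, all differentially expressed: one
#' high-coherence module (`rho = 0.8`, all up-regulated, log2 effect +2) —
#' the planted signature — and four background modules (`rho = 0.3`, two
#' down-regulated and two up-regulated at log2 effect 1.5). Counts via the
#' lognormal-Poisson model.
#'
#' @param seed Integer seed.
#' @return As [simulate_expression()].
#' @export
simulate_cesc_like <- function(seed = 1) {
  simulate_expression(
    n_genes = 2000, n_control = 22, n_case = 253,
    n_modules = 5, genes_per_module = 40,
    within_module_rho = c(0.3, 0.3, 0.3, 0.8, 0.3),
    de_fraction = 1,
    log2_effect = c(-1.5, -1.5, 1.5, 2, 1.5),
    noise_sd = 1,
    count_model = "lognormal_counts",
    seed = seed
  )
}

#' Planted signature module of a simulation truth
#' @param truth The `truth` element returned by [simulate_expression()].
#' @param module Module index (defaults to the module with the highest
#'   index of those marked; pass explicitly for presets — module 4 in
#'   [simulate_cesc_like()]).
#' @return Character vector of gene IDs.
#' @export
planted_module_genes <- function(truth, module) {
  truth$module$gene_id[truth$module$module == module]
}
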