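# fixtures and independent oracles shared across test files

# two well-separated Gaussian blobs, rows = objects
two_blobs <- function(n_per = 20, S = 5, center = 10, sd = 0.5, seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * S, center, sd), n_per),
               matrix(rnorm(n_per * S, -center, sd), n_per))
  })
  rownames(X) <- paste0("g", seq_len(2 * n_per))
  X
}

# small log-scale expression fixture with two groups
gaussian_expression <- function(n_genes = 200, n1 = 8, n2 = 8, seed = 1,
                                effect_genes = integer(0), effect = 0) {
  withr::with_seed(seed, {
    Y <- matrix(rnorm(n_genes * (n1 + n2), mean = 8, sd = 1), n_genes)
    if (length(effect_genes) > 0) {
      Y[effect_genes, (n1 + 1):(n1 + n2)] <-
        Y[effect_genes, (n1 + 1):(n1 + n2)] + effect
    }
  })
  dimnames(Y) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n1 + n2)))
  attr(Y, "value_scale") <- "other"
  list(y = Y,
       groups = group_labels(colnames(Y),
                             rep(c("control", "case"), c(n1, n2))))
}

# all partitions of n objects into at most kmax non-empty clusters, as a
# matrix of canonical label rows (first-occurrence numbering, deduplicated)
enum_partitions <- function(n, kmax = 3) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(kmax)), n)))[, n:1, drop = FALSE]
  canon <- t(apply(grid, 1, function(l) match(l, unique(l))))
  unique(canon)
}

# all permutations of a vector (for tiny exhaustive matching oracles)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# independent O(n^2) pair-counting oracle over explicit object pairs
oracle_pair_counts <- function(la, lb) {
  n <- length(la)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa) n10 <- n10 + 1
      else if (sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

# independent oracle for jaccard / fm / mca on two label vectors; mca by
# exhaustive enumeration of injective cluster matchings
oracle_indices <- function(la, lb) {
  pc <- oracle_pair_counts(la, lb)
  jac <- if (sum(pc[c("n11", "n10", "n01")]) > 0) {
    pc["n11"] / sum(pc[c("n11", "n10", "n01")])
  } else 0
  f1 <- pc["n11"] + pc["n10"]
  f2 <- pc["n11"] + pc["n01"]
  fm <- if (f1 > 0 && f2 > 0) pc["n11"] / sqrt(f1 * f2) else 0
  ka <- max(la)
  kb <- max(lb)
  cont <- matrix(0, ka, kb)
  for (i in seq_along(la)) cont[la[i], lb[i]] <- cont[la[i], lb[i]] + 1
  # pad to square and maximise over all permutations
  kk <- max(ka, kb)
  sq <- matrix(0, kk, kk)
  sq[seq_len(ka), seq_len(kb)] <- cont
  best <- 0
  for (p in perms(seq_len(kk))) {
    best <- max(best, sum(sq[cbind(seq_len(kk), p)]))
  }
  c(jaccard = unname(jac), fm = unname(fm), mca = best / length(la))
}

# brute-force non-dominated set (maximization) over the rows of a matrix
oracle_pareto_set <- function(scores) {
  n <- nrow(scores)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(scores[j, ] >= scores[i, ]) &&
          any(scores[j, ] > scores[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

# gene-set Jaccard between two character vectors
set_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# write a small expression TSV by hand (independent of write_expression)
write_raw_tsv <- function(lines, path) {
  writeLines(lines, path)
  path
}
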