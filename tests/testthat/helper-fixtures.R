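# Shared fixtures, built in code at test time.

# small expression dataset: p genes, two conditions, iid noise
make_dataset <- function(p = 5L, n1 = 10L, n2 = 10L, seed = 1L,
                         values = NULL) {
  genes <- sprintf("g%02d", seq_len(p))
  samples <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  if (is.null(values)) {
    values <- withr::with_seed(seed,
      matrix(rnorm(p * (n1 + n2)), p, n1 + n2))
  }
  dimnames(values) <- list(genes, samples)
  conds <- setNames(rep(c("c1", "c2"), c(n1, n2)), samples)
  expression_dataset(values, conds)
}

# barbell graph: two cliques of size k joined by one bridge edge
barbell_edges <- function(k = 20L) {
  left <- sprintf("L%02d", seq_len(k))
  right <- sprintf("R%02d", seq_len(k))
  pairs <- function(v) t(combn(v, 2L))
  e <- rbind(pairs(left), pairs(right), c(left[1L], right[1L]))
  suppressMessages(edge_list(e[, 1L], e[, 2L]))
}

# Gaussian-graphical-model data on a cycle: precision with known partial
# correlations, plus the closed-form partial correlation oracle
cycle_ggm <- function(p = 10L, rho = 0.25, n = 500L, seed = 42L) {
  genes <- sprintf("g%02d", seq_len(p))
  Omega <- diag(p)
  for (i in seq_len(p)) {
    j <- if (i == p) 1L else i + 1L
    Omega[i, j] <- Omega[j, i] <- -rho
  }
  # partial correlation between i,j = -Omega_ij / sqrt(Omega_ii Omega_jj)
  pc <- -Omega / sqrt(tcrossprod(diag(Omega)))
  diag(pc) <- 0
  dimnames(pc) <- list(genes, genes)
  Sigma <- solve(Omega)
  x <- withr::with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    t(z %*% chol(Sigma))
  })
  dimnames(x) <- list(genes, sprintf("s%03d", seq_len(n)))
  support <- (Omega != 0) * 1
  diag(support) <- 0
  dimnames(support) <- list(genes, genes)
  list(x = x, partial = pc, support = support, genes = genes)
}

# fixed small influence structure for variance-component tests
fixed_lambda <- function(p = 6L, seed = 7L) {
  A <- withr::with_seed(seed, {
    A <- matrix(0, p, p)
    A[lower.tri(A)] <- rbinom(p * (p - 1) / 2, 1, 0.4) *
      runif(p * (p - 1) / 2, 0.2, 0.5)
    A
  })
  genes <- sprintf("g%02d", seq_len(p))
  dimnames(A) <- list(genes, genes)
  solve(diag(p) - A)
}

expect_no_cross_cluster <- function(A, partition) {
  cl <- setNames(partition$cluster, partition$gene)
  nz <- which(A != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    g <- rownames(A)
    expect_true(all(cl[g[nz[, 1]]] == cl[g[nz[, 2]]]))
  } else {
    succeed()
  }
}
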