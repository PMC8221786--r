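make_wset <- function(A_list, partition = NULL) {
  Lambda <- lapply(A_list, function(A) solve(diag(nrow(A)) - A))
  Lambda <- lapply(seq_along(A_list), function(i) {
    L <- Lambda[[i]]; dimnames(L) <- dimnames(A_list[[i]]); L
  })
  names(Lambda) <- names(A_list)
  structure(list(A = A_list, Lambda = Lambda, directed = FALSE,
                 lambda_used = NA, partition = partition),
            class = "weighted_adjacency_set")
}

test_that("mean coefficients solve Lambda beta = ybar", {
  ds <- make_dataset(p = 2L, n1 = 4L, n2 = 4L, seed = 1L)
  genes <- ds$genes
  A0 <- matrix(0, 2, 2, dimnames = list(genes, genes))
  wset <- make_wset(list(c1 = A0, c2 = A0))
  beta <- fit_means(ds, wset)
  expect_equal(beta$c1, rowMeans(ds$values[, 1:4]), tolerance = 1e-12)

  # triangular influence: ybar = (1, 1.5), Lambda = [[1,0],[0.5,1]]
  vals <- cbind(matrix(c(1, 1.5), 2, 4), matrix(0, 2, 4))
  vals <- vals + 0  # exact means in condition 1
  ds2 <- make_dataset(p = 2L, values = vals, n1 = 4L, n2 = 4L)
  A <- matrix(c(0, 0.5, 0, 0), 2, 2, dimnames = list(genes, genes))
  wset2 <- make_wset(list(c1 = A, c2 = A))
  beta2 <- fit_means(ds2, wset2)
  expect_equal(unname(beta2$c1), c(1, 1.0), tolerance = 1e-12)

  # duplicating every sample leaves the estimate unchanged
  dup_vals <- cbind(ds$values[, rep(1:4, 2)], ds$values[, rep(5:8, 2)])
  colnames(dup_vals) <- sprintf("s%02d", 1:16)
  dup <- expression_dataset(dup_vals,
    setNames(rep(c("c1", "c2"), each = 8L), colnames(dup_vals)))
  expect_equal(fit_means(dup, wset)$c1, beta$c1)
})

test_that("REHE recovers exactly-constructed variance components", {
  L <- fixed_lambda(p = 6L)
  H <- L %*% t(L)
  S <- 0.3 * H + 0.7 * diag(6L)
  vc <- rehe_estimate(list(c1 = S, c2 = S), list(c1 = L, c2 = L),
                      c(c1 = 10L, c2 = 12L))
  expect_equal(vc$sigma2_g, 0.3, tolerance = 1e-8)
  expect_equal(vc$sigma2_e, 0.7, tolerance = 1e-8)

  zero <- matrix(0, 6L, 6L)
  vc0 <- rehe_estimate(list(c1 = zero), list(c1 = L), c(c1 = 10L))
  expect_equal(vc0$sigma2_g, 0, tolerance = 1e-12)
  expect_equal(vc0$sigma2_e, 0, tolerance = 1e-12)
})

test_that("REHE projects onto the nonnegative quadrant correctly", {
  L <- fixed_lambda(p = 5L, seed = 3L)
  H <- L %*% t(L)
  # covariance poorer than white noise along H: pushes sigma2_g negative
  S <- 1.0 * diag(5L) - 0.05 * H
  vc <- rehe_estimate(list(c1 = S), list(c1 = L), c(c1 = 20L))
  expect_gte(vc$sigma2_g, 0)
  expect_gte(vc$sigma2_e, 0)
  # grid-search oracle: returned point beats a 50x50 grid over [0,2]^2
  grid <- seq(0, 2, length.out = 50L)
  obj <- function(a, b) {
    R <- S - a * H - b * diag(5L)
    19 * sum(R * R)
  }
  grid_min <- min(outer(grid, grid, Vectorize(obj)))
  expect_lte(vc$objective, grid_min + 1e-10)
})

test_that("REHE is consistent in a Monte-Carlo experiment", {
  p <- 30L; n <- 200L
  L <- fixed_lambda(p = p, seed = 9L)
  est <- withr::with_seed(101L, {
    t(replicate(200L, {
      gamma <- matrix(rnorm(p * n, 0, sqrt(0.5)), p, n)
      eps <- matrix(rnorm(p * n, 0, 1), p, n)
      y <- L %*% gamma + eps
      S <- cov(t(y))
      vc <- rehe_estimate(list(c1 = S), list(c1 = L), c(c1 = n))
      c(vc$sigma2_g, vc$sigma2_e)
    }))
  })
  expect_lt(abs(mean(est[, 1]) - 0.5), 0.05)
  expect_lt(abs(mean(est[, 2]) - 1.0), 0.05)
})

test_that("REML agrees with REHE at large n and dominates its likelihood", {
  p <- 20L; n <- 300L
  L <- fixed_lambda(p = p, seed = 13L)
  y <- withr::with_seed(77L, {
    gamma <- matrix(rnorm(p * n, 0, sqrt(0.5)), p, n)
    eps <- matrix(rnorm(p * n, 0, 1), p, n)
    L %*% gamma + eps
  })
  S <- cov(t(y))
  S_list <- list(c1 = S); L_list <- list(c1 = L); n_k <- c(c1 = n)
  rehe <- rehe_estimate(S_list, L_list, n_k)
  reml <- reml_estimate(S_list, L_list, n_k)
  expect_lt(abs(reml$sigma2_g - rehe$sigma2_g), 0.05)
  expect_lt(abs(reml$sigma2_e - rehe$sigma2_e), 0.05)

  H <- L %*% t(L)
  eig <- eigen(H, symmetric = TRUE)
  s_diag <- diag(t(eig$vectors) %*% S %*% eig$vectors)
  ll <- function(a, b) {
    v <- a * eig$values + b
    -0.5 * (n - 1) * sum(log(v) + s_diag / v)
  }
  expect_gte(ll(reml$sigma2_g, reml$sigma2_e),
             ll(max(rehe$sigma2_g, 1e-8), max(rehe$sigma2_e, 1e-8)))
})

test_that("REML Newton solution matches a derivative-free optimizer", {
  for (i in 1:10) {
    p <- 8L; n <- 60L
    L <- fixed_lambda(p = p, seed = 100L + i)
    y <- withr::with_seed(200L + i, {
      gamma <- matrix(rnorm(p * n, 0, sqrt(0.4)), p, n)
      eps <- matrix(rnorm(p * n, 0, sqrt(0.8)), p, n)
      L %*% gamma + eps
    })
    S <- cov(t(y))
    reml <- reml_estimate(list(c1 = S), list(c1 = L), c(c1 = n))
    H <- L %*% t(L)
    eig <- eigen(H, symmetric = TRUE)
    s_diag <- diag(t(eig$vectors) %*% S %*% eig$vectors)
    nll <- function(theta) {
      v <- exp(theta[1]) * eig$values + exp(theta[2])
      0.5 * (n - 1) * sum(log(v) + s_diag / v)
    }
    opt <- optim(log(c(0.4, 0.8)), nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000L))
    expect_lt(abs(reml$sigma2_g - exp(opt$par[1])), 1e-4)
    expect_lt(abs(reml$sigma2_e - exp(opt$par[2])), 1e-4)
  }
})

test_that("identity influence makes the components non-identifiable", {
  p <- 5L
  I5 <- diag(p)
  S <- 1.5 * I5
  expect_error(rehe_estimate(list(c1 = S), list(c1 = I5), c(c1 = 10L)),
               "not identifiable")
  expect_error(reml_estimate(list(c1 = S), list(c1 = I5), c(c1 = 10L)),
               "not identifiable")
})

test_that("variance-component bias shrinks as n grows", {
  p <- 12L
  L <- fixed_lambda(p = p, seed = 21L)
  bias_at <- function(n) {
    est <- withr::with_seed(300L + n, {
      t(replicate(40L, {
        gamma <- matrix(rnorm(p * n, 0, sqrt(0.5)), p, n)
        eps <- matrix(rnorm(p * n, 0, 1), p, n)
        S <- cov(t(L %*% gamma + eps))
        vc <- rehe_estimate(list(c1 = S), list(c1 = L), c(c1 = n))
        c(vc$sigma2_g, vc$sigma2_e)
      }))
    })
    abs(colMeans(est) - c(0.5, 1.0))
  }
  b <- vapply(c(50L, 200L, 800L), bias_at, numeric(2L))
  expect_true(all(diff(b[1, ]) < 0.05))  # near-monotone decreasing
  expect_true(all(diff(b[2, ]) < 0.05))
  expect_lt(b[1, 3], b[1, 1] + 0.02)
  expect_lt(b[2, 3], b[2, 1] + 0.02)
})

test_that("pathway statistic matches direct arithmetic and invariances", {
  genes <- c("g1", "g2")
  I2 <- diag(2L); dimnames(I2) <- list(genes, genes)
  vc <- structure(list(sigma2_g = 0, sigma2_e = 10, method = "REHE",
                       vcov = NULL), class = "variance_components")
  # Cov(beta_hat_k) = sigma2_e I / n_k = 0.5 I with n_k = 20
  beta <- list(c1 = c(0, 0), c2 = c(1, 1))
  n_k <- c(c1 = 20L, c2 = 20L)
  res <- pathway_test(beta, list(c1 = I2, c2 = I2), vc, n_k, c(1, 1))
  # l C l' = 0.5*2 + 0.5*2 = 2, so T = 2 / sqrt(2)
  expect_equal(res$stat, 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$df, 38)
  expect_equal(res$size, 2L)

  # identical fits give a null statistic with p = 1
  res0 <- pathway_test(list(c1 = beta$c2, c2 = beta$c2),
                       list(c1 = I2, c2 = I2), vc, n_k, c(1, 1))
  expect_equal(res0$stat, 0)
  expect_equal(res0$pvalue, 1)

  # scaling all data by c scales beta and sqrt(C) alike: T invariant
  cc <- 3
  vc_sc <- structure(list(sigma2_g = 0, sigma2_e = 10 * cc^2,
                          method = "REHE", vcov = NULL),
                     class = "variance_components")
  res_sc <- pathway_test(lapply(beta, `*`, cc), list(c1 = I2, c2 = I2),
                         vc_sc, n_k, c(1, 1))
  expect_equal(res_sc$stat, res$stat, tolerance = 1e-12)

  expect_error(pathway_test(beta, list(c1 = I2, c2 = I2), vc, n_k,
                            c(0, 0)), "no member")
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(rep(1, 5L)), rep(1, 5L))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute-force step-up oracle on random vectors
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
  }
  withr::with_seed(8L, {
    for (i in 1:100) {
      p <- runif(sample(1:40, 1L))
      q <- bh_adjust(p)
      expect_equal(q, step_up(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(diff(q[order(p)]) > -1e-12))  # monotone in p-rank
    }
  })
})
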