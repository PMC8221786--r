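test_that("full shrinkage in discovery mode yields a zero block", {
  ds <- make_dataset(p = 6L, n1 = 15L, n2 = 15L, seed = 2L)
  x <- ds$values[, 1:15]
  known <- matrix(0, 6L, 6L, dimnames = list(ds$genes, ds$genes))
  fit <- estimate_undirected(x, known, penalty = 1e6, nonedge_penalty = 1)
  expect_equal(unname(fit$A), matrix(0, 6L, 6L))
  L <- influence_matrix(fit$A)
  expect_equal(unname(L), diag(6L))
})

test_that("known-support estimates recover cycle partial correlations", {
  gm <- cycle_ggm(p = 10L, rho = 0.25, n = 500L, seed = 42L)
  fit <- estimate_undirected(gm$x, gm$support)
  # support containment: no weight outside the allowed edges
  expect_true(all(fit$A[gm$support == 0] == 0))
  # estimated weights close to the generating partial correlations,
  # with matching signs on every true edge
  on_edge <- gm$support == 1
  expect_lt(max(abs(fit$A[on_edge] - gm$partial[on_edge])), 0.1)
  expect_true(all(sign(fit$A[on_edge]) == sign(gm$partial[on_edge])))
  expect_true(isSymmetric(fit$A))
  expect_equal(unname(diag(fit$A)), rep(0, 10L))
})

test_that("discovery mode recovers an edge hidden from the knowledge base", {
  gm <- cycle_ggm(p = 10L, rho = 0.25, n = 500L, seed = 7L)
  incomplete <- gm$support
  incomplete["g01", "g02"] <- incomplete["g02", "g01"] <- 0
  fit <- estimate_undirected(gm$x, incomplete, penalty = 0.05,
                             nonedge_penalty = 1)
  expect_gt(abs(fit$A["g01", "g02"]), 0.05)
  expect_true(sign(fit$A["g01", "g02"]) == sign(gm$partial["g01", "g02"]))
})

test_that("degenerate and invalid inputs error informatively", {
  ds <- make_dataset(p = 4L, n1 = 10L, n2 = 10L)
  x <- ds$values[, 1:10]
  known <- matrix(1, 4L, 4L, dimnames = list(ds$genes, ds$genes))
  diag(known) <- 0
  expect_error(estimate_undirected(x, known, penalty = -1), "nonnegative")
  x2 <- x; x2[2, ] <- 5
  expect_error(estimate_undirected(x2, known), "g02")
})

test_that("directed estimation regresses children on parents only", {
  genes <- c("a", "b", "c")
  n <- 1000L
  x <- withr::with_seed(21L, {
    a <- rnorm(n)
    b <- 0.5 * a + rnorm(n, sd = 0.5)
    c <- rnorm(n)
    rbind(a = a, b = b, c = c)
  })
  dimnames(x) <- list(genes, sprintf("s%d", 1:n))
  known <- matrix(0, 3L, 3L, dimnames = list(genes, genes))
  known["a", "b"] <- 1  # a -> b
  fit <- estimate_directed(x, known, scale = FALSE)
  expect_lt(abs(fit$A["b", "a"] - 0.5), 0.05)
  expect_equal(sum(fit$A["a", ]), 0)  # parentless gene: zero row
  expect_equal(sum(fit$A["c", ]), 0)
  expect_equal(sum(fit$A != 0), 1L)

  cyc <- known; cyc["b", "a"] <- 1
  expect_error(estimate_directed(x, cyc), "cycle")
})

test_that("influence matrix matches closed forms and the Neumann series", {
  A2 <- matrix(c(0, 0.5, 0, 0), 2L, 2L,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  L2 <- influence_matrix(A2)
  expect_equal(unname(L2), matrix(c(1, 0.5, 0, 1), 2L), tolerance = 1e-10)

  # random 8-node DAG: strictly triangular adjacency is nilpotent, so
  # Lambda equals the finite Neumann sum of powers of A
  p <- 8L
  A <- withr::with_seed(5L, {
    A <- matrix(0, p, p)
    A[lower.tri(A)] <- rbinom(p * (p - 1) / 2, 1, 0.35) *
      runif(p * (p - 1) / 2, -0.6, 0.6)
    A
  })
  dimnames(A) <- list(sprintf("g%d", 1:p), sprintf("g%d", 1:p))
  L <- influence_matrix(A)
  neumann <- diag(p)
  term <- diag(p)
  for (m in seq_len(p)) {
    term <- term %*% A
    neumann <- neumann + term
  }
  expect_equal(unname(L), unname(neumann), tolerance = 1e-8)

  near_singular <- matrix(c(0, 1, 1, 0), 2L, 2L,
                          dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(influence_matrix(near_singular), "singular")
})

test_that("assembly zeroes cross-cluster entries and is identity on one block", {
  genes <- sprintf("g%d", 1:5)
  part <- tibble::tibble(gene = genes, component = c(1, 1, 1, 2, 2),
                         cluster = c(1, 1, 1, 2, 2))
  class(part) <- c("cluster_partition", class(tibble::tibble()))
  b1 <- matrix(0.3, 3, 3, dimnames = list(genes[1:3], genes[1:3]))
  diag(b1) <- 0
  b2 <- matrix(0.2, 2, 2, dimnames = list(genes[4:5], genes[4:5]))
  diag(b2) <- 0
  A <- assemble_adjacency(list(`1` = b1, `2` = b2), part, genes)
  expect_equal(sum(A[1:3, 4:5] != 0), 0L)
  expect_equal(A[genes[1:3], genes[1:3]], b1)

  single <- tibble::tibble(gene = genes, component = 1, cluster = 1)
  class(single) <- c("cluster_partition", class(tibble::tibble()))
  full <- matrix(0.1, 5, 5, dimnames = list(genes, genes))
  diag(full) <- 0
  expect_equal(assemble_adjacency(list(`1` = full), single, genes), full)

  expect_error(assemble_adjacency(list(`1` = b1), part, genes),
               "do not match")
})

test_that("clustered estimation equals per-cluster estimation reassembled", {
  # network with two disjoint components: clustering must not change the
  # estimate at all, and the influence matrix is block diagonal
  gm1 <- cycle_ggm(p = 6L, rho = 0.3, n = 120L, seed = 10L)
  gm2 <- cycle_ggm(p = 5L, rho = 0.2, n = 120L, seed = 11L)
  genes <- c(paste0("a", rownames(gm1$x)), paste0("b", rownames(gm2$x)))
  vals <- rbind(gm1$x, gm2$x)
  rownames(vals) <- genes
  n <- ncol(vals)
  conds <- setNames(rep(c("c1", "c2"), length.out = n), colnames(vals))
  ds <- expression_dataset(vals, conds)
  support <- matrix(0, 11L, 11L, dimnames = list(genes, genes))
  support[1:6, 1:6] <- gm1$support
  support[7:11, 7:11] <- gm2$support
  adj <- structure(list(matrix = support, directed = FALSE),
                   class = "binary_adjacency")

  part <- cluster_network(adj, max_size = 8L, seed = 1L)
  whole <- estimate_adjacency(ds, adj, partition = trivial_partition(adj))
  split <- estimate_adjacency(ds, adj, partition = part)
  for (k in names(whole$A)) {
    expect_equal(split$A[[k]], whole$A[[k]], tolerance = 1e-8)
    expect_equal(split$Lambda[[k]], whole$Lambda[[k]], tolerance = 1e-8)
    expect_no_cross_cluster(split$A[[k]], part)
    # blockwise inverse equals the full inverse
    expect_equal(split$Lambda[[k]],
                 solve(diag(11L) - split$A[[k]]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("estimation is equivariant under gene relabeling", {
  gm <- cycle_ggm(p = 8L, rho = 0.25, n = 200L, seed = 33L)
  fit <- estimate_undirected(gm$x, gm$support)
  perm <- withr::with_seed(1L, sample(8L))
  fit_p <- estimate_undirected(gm$x[perm, ], gm$support[perm, perm])
  expect_equal(fit_p$A, fit$A[perm, perm], tolerance = 1e-10)
})

test_that("the auto penalty follows the closed-form scaling", {
  expect_equal(netenrich:::resolve_penalty("auto", 100L, 50L, 1),
               sqrt(log(100) / 50))
  expect_equal(netenrich:::resolve_penalty("auto", 100L, 50L, 2),
               2 * sqrt(log(100) / 50))
  expect_equal(netenrich:::resolve_penalty(0.3, 10L, 10L, 1), 0.3)
})
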