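#' Estimate one undirected weighted-adjacency block
#'
#' Neighborhood regression with structural constraints: each gene is
#' regressed on the other genes of the cluster, with penalty weight 0 on
#' known-edge partners and weight 1 on non-edge partners. With the default
#' infinite non-edge penalty, non-edge partners are excluded and the
#' regression is ordinary least squares on the known neighborhood; with a
#' finite non-edge penalty a lasso (via glmnet) admits data-supported edges
#' absent from the interaction knowledge. Coefficients are converted to
#' partial-correlation-scaled weights by the signed geometric mean rule:
#' `w(i,j) = sign * sqrt(|b_ij * b_ji|)` when the two regression
#' coefficients agree in sign, else 0.
#'
#' @param x Numeric matrix, genes x samples, one condition and one cluster.
#' @param known 0/1 symmetric matrix over the same genes (known edges).
#' @param penalty Nonnegative lasso penalty, or "auto" for
#'   `penalty_c * sqrt(log(p) / n)`.
#' @param nonedge_penalty Penalty factor for partners without a known edge;
#'   `Inf` (default) excludes them entirely, a finite value enables
#'   discovery of edges missing from the knowledge base.
#' @param penalty_c Scale constant for the "auto" penalty (default 1).
#' @param scale Standardize each gene to unit variance before estimation
#'   (genes are always centered).
#' @return List with `A` (symmetric weight matrix, zero diagonal) and
#'   `lambda` (penalty used).
#' @export
estimate_undirected <- function(x, known, penalty = "auto",
                                nonedge_penalty = Inf, penalty_c = 1,
                                scale = TRUE) {
  p <- nrow(x)
  n <- ncol(x)
  if (n < 3L) stop("need >= 3 samples to estimate a block", call. = FALSE)
  genes <- rownames(x)
  if (!identical(dim(known), c(p, p))) {
    stop("`known` dimensions do not match the data block", call. = FALSE)
  }
  xs <- center_scale_genes(x, scale = scale)
  lam <- resolve_penalty(penalty, p, n, penalty_c)
  B <- matrix(0, p, p, dimnames = list(genes, genes))
  if (p >= 2L) {
    for (i in seq_len(p)) {
      is_edge <- known[i, -i] > 0
      if (is.infinite(nonedge_penalty)) {
        partners <- setdiff(seq_len(p), i)[is_edge]
        if (length(partners) == 0L) next
        X <- t(xs[partners, , drop = FALSE])
        B[i, partners] <- ols_coef(X, xs[i, ])
      } else {
        others <- setdiff(seq_len(p), i)
        X <- t(xs[others, , drop = FALSE])
        pf <- ifelse(is_edge, 0, nonedge_penalty)
        if (all(pf == 0)) {
          B[i, others] <- ols_coef(X, xs[i, ])
        } else if (ncol(X) == 1L) {
          # closed-form lasso for a single predictor
          b <- ols_coef(X, xs[i, ])
          thr <- lam * pf * n / sum(X^2)
          B[i, others] <- sign(b) * max(abs(b) - thr, 0)
        } else {
          fit <- glmnet::glmnet(X, xs[i, ], lambda = lam,
                                penalty.factor = pf,
                                standardize = FALSE, intercept = FALSE)
          B[i, others] <- as.numeric(fit$beta)
        }
      }
    }
  }
  # signed geometric-mean symmetrization (partial-correlation scale)
  sgn <- sign(B)
  agree <- sgn * t(sgn) > 0
  A <- ifelse(agree, sgn * sqrt(abs(B * t(B))), 0)
  diag(A) <- 0
  dimnames(A) <- list(genes, genes)
  list(A = A, lambda = lam)
}

center_scale_genes <- function(x, scale = TRUE) {
  mu <- rowMeans(x)
  xs <- x - mu
  if (scale) {
    sds <- apply(xs, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant gene(s) in condition block: ",
           paste(utils::head(rownames(x)[sds == 0], 5L), collapse = ", "),
           call. = FALSE)
    }
    xs <- xs / sds
  }
  xs
}

resolve_penalty <- function(penalty, p, n, penalty_c) {
  if (identical(penalty, "auto")) {
    return(penalty_c * sqrt(log(max(p, 2L)) / n))
  }
  penalty <- as.numeric(penalty)
  if (is.na(penalty) || penalty < 0) {
    stop("`penalty` must be nonnegative or \"auto\"", call. = FALSE)
  }
  penalty
}

ols_coef <- function(X, y) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  b[is.na(b)] <- 0
  b
}

#' Estimate one directed weighted-adjacency block
#'
#' For a known directed acyclic structure, each gene is regressed by
#' ordinary least squares on its parents; the weight matrix carries the
#' regression coefficient at (child, parent) and exact zeros elsewhere.
#'
#' @param x Numeric matrix, genes x samples (one condition, one cluster).
#' @param known 0/1 matrix with `known[a, b] = 1` for a directed edge
#'   a -> b (a is a parent of b); must be acyclic on this block.
#' @param scale Standardize genes before estimation (genes always centered).
#' @return List with `A` (child-by-parent weights) and `lambda` (NA; no
#'   penalty is used on a known DAG).
#' @export
estimate_directed <- function(x, known, scale = TRUE) {
  p <- nrow(x)
  genes <- rownames(x)
  g <- igraph::graph_from_adjacency_matrix(known, mode = "directed")
  if (!igraph::is_dag(g)) {
    scc <- igraph::components(g, mode = "strong")
    cyc <- names(scc$membership)[scc$membership ==
                                   which(scc$csize > 1)[1L]]
    stop("directed structure contains a cycle through: ",
         paste(utils::head(cyc, 10L), collapse = " -> "), call. = FALSE)
  }
  xs <- center_scale_genes(x, scale = scale)
  A <- matrix(0, p, p, dimnames = list(genes, genes))
  for (i in seq_len(p)) {
    parents <- which(known[, i] > 0)  # edges parent -> i
    if (length(parents) == 0L) next
    X <- t(xs[parents, , drop = FALSE])
    A[i, parents] <- ols_coef(X, xs[i, ])
  }
  list(A = A, lambda = NA_real_)
}

#' Assemble per-cluster blocks into a full weighted adjacency
#'
#' @param blocks Named list (by cluster id) of weight matrices with gene
#'   dimnames.
#' @param partition A `cluster_partition` covering the gene universe.
#' @param universe Canonical gene order for the assembled matrix.
#' @return Full matrix with cross-cluster entries exactly zero.
#' @export
assemble_adjacency <- function(blocks, partition, universe) {
  p <- length(universe)
  A <- matrix(0, p, p, dimnames = list(universe, universe))
  cl_genes <- partition_clusters(partition)
  if (!setequal(names(blocks), names(cl_genes))) {
    stop("blocks do not match the partition's cluster ids", call. = FALSE)
  }
  for (cl in names(blocks)) {
    g <- cl_genes[[cl]]
    blk <- blocks[[cl]]
    if (!setequal(rownames(blk), g)) {
      stop("block ", cl, " dimnames do not match the partition",
           call. = FALSE)
    }
    A[g, g] <- blk[g, g]
  }
  A
}

#' Influence matrix of a weighted adjacency
#'
#' The influence matrix propagates each gene's baseline effect through the
#' network: `Lambda = (I - A)^{-1}`. With an active clustering partition
#' the inverse is computed blockwise (the full inverse of a block-diagonal
#' `I - A` is the concatenation of blockwise inverses).
#'
#' @param A Weighted adjacency matrix (zero diagonal).
#' @param partition Optional `cluster_partition`; blockwise inversion.
#' @param tol Residual tolerance for the inverse check (default 1e-8).
#' @return The influence matrix, same dimnames as `A`.
#' @export
influence_matrix <- function(A, partition = NULL, tol = 1e-8) {
  genes <- rownames(A)
  p <- nrow(A)
  invert <- function(block) {
    M <- diag(nrow(block)) - block
    rc <- rcond(M)
    if (!is.finite(rc) || rc < 1e-12) {
      stop("I - A is near-singular (condition estimate > 1e12); ",
           "use a stronger penalty or rescale the weights", call. = FALSE)
    }
    solve(M)
  }
  if (is.null(partition)) {
    L <- invert(A)
    dimnames(L) <- dimnames(A)
  } else {
    L <- matrix(0, p, p, dimnames = dimnames(A))
    for (g in partition_clusters(partition)) {
      L[g, g] <- invert(A[g, g, drop = FALSE])
    }
  }
  resid <- max(abs((diag(p) - A) %*% L - diag(p)))
  if (resid > tol) {
    stop("influence-matrix residual ", format(resid),
         " exceeds tolerance ", format(tol), call. = FALSE)
  }
  L
}

#' Estimate condition-specific weighted adjacency matrices
#'
#' For each condition, estimates the weighted adjacency constrained by the
#' known 0-1 structure, per cluster of the partition, and reassembles the
#' blocks into a block-diagonal full-network estimate. Undirected networks
#' use constrained neighborhood regression ([estimate_undirected()]);
#' directed acyclic networks use parent regressions
#' ([estimate_directed()]).
#'
#' @param data An [expression_dataset()].
#' @param adj A `binary_adjacency` over the same gene universe.
#' @param partition A `cluster_partition`, or `NULL` for no clustering
#'   (one cluster per connected component is still used for block
#'   inversion efficiency; estimation is identical).
#' @inheritParams estimate_undirected
#' @return Object of class `weighted_adjacency_set`: list with `A` (named
#'   list of per-condition matrices), `Lambda` (influence matrices),
#'   `directed`, `lambda_used` (per condition), `partition`.
#' @export
estimate_adjacency <- function(data, adj, partition = NULL,
                               penalty = "auto", nonedge_penalty = Inf,
                               penalty_c = 1, scale = TRUE) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(adj, "binary_adjacency"))
  if (!identical(data$genes, rownames(adj$matrix))) {
    stop("gene order of expression data and adjacency differ", call. = FALSE)
  }
  if (is.null(partition)) partition <- trivial_partition(adj)
  conds <- unique(unname(data$conditions))
  cl_genes <- partition_clusters(partition)
  A_list <- list()
  lambda_used <- stats::setNames(numeric(length(conds)), conds)
  for (k in conds) {
    xk <- data$values[, data$conditions == k, drop = FALSE]
    blocks <- list()
    lam_k <- NA_real_
    for (cl in names(cl_genes)) {
      g <- cl_genes[[cl]]
      known_blk <- adj$matrix[g, g, drop = FALSE]
      x_blk <- xk[g, , drop = FALSE]
      no_partners <- sum(known_blk) == 0 && is.infinite(nonedge_penalty)
      if (length(g) == 1L || no_partners) {
        blocks[[cl]] <- matrix(0, length(g), length(g),
                               dimnames = list(g, g))
        next
      }
      fit <- if (adj$directed) {
        estimate_directed(x_blk, known_blk, scale = scale)
      } else {
        estimate_undirected(x_blk, known_blk, penalty = penalty,
                            nonedge_penalty = nonedge_penalty,
                            penalty_c = penalty_c, scale = scale)
      }
      blocks[[cl]] <- fit$A
      lam_k <- fit$lambda
    }
    A_k <- assemble_adjacency(blocks, partition, data$genes)
    A_list[[k]] <- A_k
    lambda_used[k] <- lam_k
  }
  Lambda <- lapply(A_list, influence_matrix, partition = partition)
  structure(list(A = A_list, Lambda = Lambda, directed = adj$directed,
                 lambda_used = lambda_used, partition = partition),
            class = "weighted_adjacency_set")
}

#' @export
print.weighted_adjacency_set <- function(x, ...) {
  cat("<weighted_adjacency_set> ", length(x$A), " condition(s), ",
      nrow(x$A[[1L]]), " genes, ",
      if (x$directed) "directed" else "undirected", "\n", sep = "")
  invisible(x)
}
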