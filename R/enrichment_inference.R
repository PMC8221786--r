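#' Per-condition mean coefficients of the latent-variable network model
#'
#' The model for a sample in condition k is
#' `y = Lambda_k beta_k + Lambda_k gamma + eps`, with `gamma ~ N(0,
#' sigma2_g I)` propagated through the network and `eps ~ N(0, sigma2_e
#' I)` residual noise. The generalized-least-squares estimate under the
#' common within-condition design is `beta_hat_k = Lambda_k^{-1} ybar_k`,
#' with `ybar_k` the per-gene sample mean in condition k.
#'
#' @param data An [expression_dataset()].
#' @param wset A `weighted_adjacency_set` (provides each `Lambda_k`).
#' @return Named list (by condition) of mean-coefficient vectors.
#' @export
fit_means <- function(data, wset) {
  conds <- unique(unname(data$conditions))
  out <- list()
  for (k in conds) {
    idx <- data$conditions == k
    if (sum(idx) < 2L) {
      stop("condition '", k, "' has < 2 samples", call. = FALSE)
    }
    ybar <- rowMeans(data$values[, idx, drop = FALSE])
    A_k <- wset$A[[k]]
    # Lambda^{-1} = I - A, so beta_hat solves directly
    out[[k]] <- as.numeric((diag(nrow(A_k)) - A_k) %*% ybar)
    names(out[[k]]) <- data$genes
  }
  out
}

residual_covariances <- function(data) {
  conds <- unique(unname(data$conditions))
  lapply(stats::setNames(conds, conds), function(k) {
    x <- data$values[, data$conditions == k, drop = FALSE]
    stats::cov(t(x))
  })
}

condition_sizes <- function(data) {
  conds <- unique(unname(data$conditions))
  vapply(stats::setNames(conds, conds),
         function(k) sum(data$conditions == k), 0L)
}

# Frobenius inner products of the variance-structure system:
# minimize sum_k w_k || S_k - a H_k - b I ||_F^2  with H_k = Lambda_k %*%
# t(Lambda_k), w_k = n_k - 1. Returns the 2x2 Gram matrix and rhs.
vc_normal_system <- function(S_list, H_list, n_k) {
  p <- nrow(S_list[[1L]])
  G <- matrix(0, 2L, 2L)
  rhs <- numeric(2L)
  for (k in names(S_list)) {
    w <- n_k[[k]] - 1
    H <- H_list[[k]]
    G[1L, 1L] <- G[1L, 1L] + w * sum(H * H)
    G[1L, 2L] <- G[1L, 2L] + w * sum(diag(H))
    G[2L, 2L] <- G[2L, 2L] + w * p
    rhs[1L] <- rhs[1L] + w * sum(S_list[[k]] * H)
    rhs[2L] <- rhs[2L] + w * sum(diag(S_list[[k]]))
  }
  G[2L, 1L] <- G[1L, 2L]
  list(G = G, rhs = rhs, p = p)
}

check_vc_identifiable <- function(G) {
  # H proportional to I for every condition makes the Gram matrix of
  # (H, I) singular: only sigma2_g + sigma2_e would be identified
  d <- det(G)
  if (!is.finite(d) || d <= 1e-10 * G[1L, 1L] * G[2L, 2L]) {
    stop("variance components not identifiable: every Lambda_k ",
         "Lambda_k' is (numerically) proportional to the identity, so ",
         "only sigma2_g + sigma2_e is identified", call. = FALSE)
  }
}

#' Restricted Haseman-Elston variance-component estimation
#'
#' Constrained method-of-moments estimator: `(sigma2_g, sigma2_e)`
#' minimizes the weighted Frobenius discrepancy
#' `sum_k (n_k - 1) || S_k - sigma2_g Lambda_k Lambda_k' - sigma2_e I
#' ||_F^2` over the nonnegative quadrant. The unconstrained 2x2 normal
#' equations are solved first; if a component is negative, both
#' single-component boundary problems are solved and the feasible
#' minimizer returned.
#'
#' @param S_list Named list (by condition) of residual covariance matrices
#'   `S_k` (computed from `y_i - Lambda_k beta_hat_k`, i.e. the centered
#'   within-condition sample covariance).
#' @param Lambda_list Named list of influence matrices `Lambda_k`.
#' @param n_k Named vector of per-condition sample counts.
#' @return Object of class `variance_components`: list with `sigma2_g`,
#'   `sigma2_e`, `method = "REHE"`, and `objective` at the solution.
#' @export
rehe_estimate <- function(S_list, Lambda_list, n_k) {
  H_list <- lapply(Lambda_list, function(L) L %*% t(L))
  sys <- vc_normal_system(S_list, H_list, n_k)
  check_vc_identifiable(sys$G)
  objective <- function(theta) {
    val <- 0
    for (k in names(S_list)) {
      R <- S_list[[k]] - theta[1L] * H_list[[k]] - theta[2L] * diag(sys$p)
      val <- val + (n_k[[k]] - 1) * sum(R * R)
    }
    val
  }
  sol <- solve(sys$G, sys$rhs)
  if (any(sol < 0)) {
    cand <- list(
      c(0, max(0, sys$rhs[2L] / sys$G[2L, 2L])),
      c(max(0, sys$rhs[1L] / sys$G[1L, 1L]), 0)
    )
    vals <- vapply(cand, objective, 0)
    sol <- cand[[which.min(vals)]]
  }
  structure(list(sigma2_g = sol[1L], sigma2_e = sol[2L], method = "REHE",
                 objective = objective(sol), vcov = NULL),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> method = ", x$method,
      ": sigma2_g = ", format(x$sigma2_g, digits = 4L),
      ", sigma2_e = ", format(x$sigma2_e, digits = 4L), "\n", sep = "")
  invisible(x)
}

# Restricted log-likelihood (up to an additive constant) and its
# derivatives, via the eigendecompositions of H_k. eig_list entries carry
# `values` (d_j) and `s` (diagonal of U' S_k U); w = n_k - 1.
reml_loglik <- function(theta, eig_list, w_k) {
  a <- theta[1L]; b <- theta[2L]
  ll <- 0; grad <- c(0, 0); hess <- matrix(0, 2L, 2L)
  for (k in names(eig_list)) {
    d <- eig_list[[k]]$values
    s <- eig_list[[k]]$s
    w <- w_k[[k]]
    v <- a * d + b
    ll <- ll - 0.5 * w * sum(log(v) + s / v)
    grad[1L] <- grad[1L] - 0.5 * w * sum(d * (1 / v - s / v^2))
    grad[2L] <- grad[2L] - 0.5 * w * sum(1 / v - s / v^2)
    hess[1L, 1L] <- hess[1L, 1L] - 0.5 * w * sum(d^2 * (2 * s - v) / v^3)
    hess[1L, 2L] <- hess[1L, 2L] - 0.5 * w * sum(d * (2 * s - v) / v^3)
    hess[2L, 2L] <- hess[2L, 2L] - 0.5 * w * sum((2 * s - v) / v^3)
  }
  hess[2L, 1L] <- hess[1L, 2L]
  list(ll = ll, grad = grad, hess = hess)
}

#' Restricted maximum likelihood variance-component estimation
#'
#' Maximizes the restricted Gaussian log-likelihood of the
#' per-condition covariance `sigma2_g Lambda_k Lambda_k' + sigma2_e I`
#' by Newton iterations on the profile log-likelihood with analytic
#' gradient and Hessian. Nonnegativity is enforced by iterating on the
#' log scale; convergence when the relative parameter change drops below
#' `tol` (default 1e-8), with at most `max_iter` (100) iterations.
#'
#' @inheritParams rehe_estimate
#' @param init Optional starting values `(sigma2_g, sigma2_e)`; defaults
#'   to the REHE solution pushed off the boundary.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return A `variance_components` object with `method = "REML"`,
#'   `loglik`, and `vcov` (inverse observed information of
#'   `(sigma2_g, sigma2_e)` at the optimum).
#' @export
reml_estimate <- function(S_list, Lambda_list, n_k, init = NULL,
                          tol = 1e-8, max_iter = 100L) {
  H_list <- lapply(Lambda_list, function(L) L %*% t(L))
  sys <- vc_normal_system(S_list, H_list, n_k)
  check_vc_identifiable(sys$G)
  w_k <- lapply(n_k, function(n) n - 1)
  eig_list <- lapply(names(H_list), function(k) {
    e <- eigen(H_list[[k]], symmetric = TRUE)
    list(values = pmax(e$values, 0),
         s = diag(t(e$vectors) %*% S_list[[k]] %*% e$vectors))
  })
  names(eig_list) <- names(H_list)
  if (is.null(init)) {
    rehe <- rehe_estimate(S_list, Lambda_list, n_k)
    scale0 <- mean(vapply(S_list, function(S) mean(diag(S)), 0))
    init <- pmax(c(rehe$sigma2_g, rehe$sigma2_e), 1e-4 * max(scale0, 1e-8))
  }
  theta <- log(init)
  cur <- reml_loglik(exp(theta), eig_list, w_k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    x <- exp(theta)
    # chain rule to the log scale
    g_log <- cur$grad * x
    h_log <- cur$hess * tcrossprod(x) + diag(cur$grad * x)
    step <- tryCatch(-solve(h_log, g_log), error = function(e) NULL)
    if (is.null(step) || sum(step * g_log) <= 0) {
      step <- g_log / max(sqrt(sum(g_log^2)), 1e-12)  # ascent fallback
    }
    # step halving to guarantee ascent
    alpha <- 1
    repeat {
      cand <- theta + alpha * step
      new <- reml_loglik(exp(cand), eig_list, w_k)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    rel <- max(abs(exp(cand) - exp(theta)) / pmax(exp(theta), 1e-12))
    theta <- cand
    cur <- new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("REML did not converge in ", max_iter, " iterations; last ",
         "iterate (", paste(format(exp(theta), digits = 6L),
                            collapse = ", "),
         "), gradient norm ", format(sqrt(sum(cur$grad^2))), call. = FALSE)
  }
  est <- exp(theta)
  vcov <- tryCatch(solve(-cur$hess), error = function(e) NULL)
  structure(list(sigma2_g = est[1L], sigma2_e = est[2L], method = "REML",
                 loglik = cur$ll, vcov = vcov),
            class = "variance_components")
}

#' Test one pathway for enrichment between two conditions
#'
#' The contrast vector is `l = (-b' Lambda_1, b' Lambda_2)` applied to the
#' stacked mean coefficients, giving the statistic
#' `T = l beta_hat / sqrt(l C l')` where `C` is block diagonal with
#' `Cov(beta_hat_k) = Lambda_k^{-1} (sigma2_g Lambda_k Lambda_k' +
#' sigma2_e I) Lambda_k^{-T} / n_k`. The two-sided p-value uses a t
#' reference: `df = n_1 + n_2 - 2` under REHE, or a Satterthwaite-style df
#' from the REML information matrix when available.
#'
#' @param beta Named list (two conditions) of mean-coefficient vectors.
#' @param Lambda Named list of influence matrices for the same conditions.
#' @param vc A `variance_components` object.
#' @param n_k Named per-condition sample counts.
#' @param b 0/1 pathway membership indicator over the gene universe.
#' @param conditions Character pair naming the two conditions to contrast
#'   (defaults to the two in `beta`).
#' @return One-row tibble: `size`, `stat`, `df`, `pvalue`.
#' @export
pathway_test <- function(beta, Lambda, vc, n_k, b, conditions = NULL) {
  if (is.null(conditions)) conditions <- names(beta)
  if (length(conditions) != 2L) {
    stop("exactly two conditions must be contrasted", call. = FALSE)
  }
  k1 <- conditions[1L]; k2 <- conditions[2L]
  if (sum(b) == 0) stop("pathway has no member genes", call. = FALSE)
  num <- sum(b * (Lambda[[k2]] %*% beta[[k2]])) -
    sum(b * (Lambda[[k1]] %*% beta[[k1]]))
  q_g <- 0; q_e <- 0
  for (k in c(k1, k2)) {
    Lb <- crossprod(Lambda[[k]], b)     # Lambda_k' b
    q_g <- q_g + sum(Lb^2) / n_k[[k]]   # b' H_k b / n_k
    q_e <- q_e + sum(b^2) / n_k[[k]]
  }
  denom2 <- vc$sigma2_g * q_g + vc$sigma2_e * q_e
  if (!is.finite(denom2) || denom2 <= 0) {
    stop("contrast variance is not positive; degenerate fit", call. = FALSE)
  }
  df <- n_k[[k1]] + n_k[[k2]] - 2
  if (identical(vc$method, "REML") && !is.null(vc$vcov)) {
    q <- c(q_g, q_e)
    var_denom2 <- drop(t(q) %*% vc$vcov %*% q)
    if (is.finite(var_denom2) && var_denom2 > 0) {
      df <- 2 * denom2^2 / var_denom2
      df <- min(max(df, 1), n_k[[k1]] + n_k[[k2]] - 2)
    }
  }
  stat <- num / sqrt(denom2)
  tibble::tibble(size = sum(b != 0), stat = stat, df = df,
                 pvalue = 2 * stats::pt(-abs(stat), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 and monotone in p-rank.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
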