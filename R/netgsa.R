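#' Network-based pathway enrichment, end to end
#'
#' Runs the full topology-based enrichment pipeline: restrict the edge
#' list and pathways to the expression gene universe, build the 0-1
#' adjacency, partition oversized components into clusters (on by
#' default), estimate condition-specific weighted adjacency matrices per
#' cluster and reassemble them block-diagonally, compute influence
#' matrices, estimate the variance components (REHE by default, REML
#' optionally), test each pathway between two conditions, and adjust
#' p-values by Benjamini-Hochberg.
#'
#' Under `estimator = "reml"` the variance components are, by default,
#' re-estimated for each pathway on the submatrices restricted to the
#' pathway members plus their direct network neighbors
#' (`reml_scope = "pathway"`); `reml_scope = "network"` fits them once on
#' the whole network.
#'
#' @param data An [expression_dataset()].
#' @param edges An [edge_list()] of known interactions, or `NULL` to rely
#'   purely on discovery mode (requires a finite `nonedge_penalty`).
#' @param pathways A [pathway_set()].
#' @param estimator `"rehe"` (default) or `"reml"`.
#' @param cluster Apply community-based clustering to oversized
#'   components (default `TRUE`).
#' @param max_size Cluster size cap (default 1000).
#' @param conditions Optional character pair selecting the two conditions
#'   to contrast; defaults to the two conditions of the data (error if
#'   more than two and not specified).
#' @param fdr FDR significance cut-off used for the `significant` flag
#'   (default 0.05).
#' @param penalty,nonedge_penalty,penalty_c,scale Passed to
#'   [estimate_adjacency()].
#' @param reml_scope `"pathway"` (default) or `"network"`; see Details.
#' @param seed Integer seed for the stochastic clustering algorithms.
#' @return Object of class `netgsa_result`; `tidy()` returns the
#'   per-pathway table (`pathway`, `size`, `stat`, `df`, `pvalue`,
#'   `qvalue`, `significant`), `glance()` a one-row model summary, and
#'   `autoplot()` an enrichment plot. The object also carries the fitted
#'   adjacency set, the partition, the variance components and a run log.
#' @export
run_netgsa <- function(data, edges, pathways,
                       estimator = c("rehe", "reml"),
                       cluster = TRUE, max_size = 1000L,
                       conditions = NULL, fdr = 0.05,
                       penalty = "auto", nonedge_penalty = Inf,
                       penalty_c = 1, scale = TRUE,
                       reml_scope = c("pathway", "network"),
                       seed = 1L) {
  estimator <- match.arg(estimator)
  reml_scope <- match.arg(reml_scope)
  stopifnot(inherits(data, "expression_dataset"))
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
    timing[[name]] <<- proc.time()[["elapsed"]] - t1
    res
  }

  restricted <- stage("validate",
                      restrict_to_universe(edges, pathways, data$genes))
  edges <- restricted$edges
  pathways <- restricted$pathways
  adj <- stage("adjacency", build_binary_adjacency(edges, data$genes))
  partition <- stage("cluster", if (cluster) {
    cluster_network(adj, max_size = max_size, seed = seed)
  } else {
    trivial_partition(adj)
  })
  wset <- stage("estimate",
                estimate_adjacency(data, adj, partition,
                                   penalty = penalty,
                                   nonedge_penalty = nonedge_penalty,
                                   penalty_c = penalty_c, scale = scale))
  if (is.null(conditions)) {
    conds <- unique(unname(data$conditions))
    if (length(conds) != 2L) {
      stop("data has ", length(conds), " conditions; supply `conditions` ",
           "as a pair to contrast", call. = FALSE)
    }
    conditions <- conds
  }
  beta <- stage("means", fit_means(data, wset))
  S_list <- residual_covariances(data)
  n_k <- condition_sizes(data)

  vc <- NULL
  if (estimator == "rehe" || reml_scope == "network") {
    vc <- stage("variance", if (estimator == "rehe") {
      rehe_estimate(S_list, wset$Lambda, n_k)
    } else {
      reml_estimate(S_list, wset$Lambda, n_k)
    })
  }

  memb <- pathways$membership
  bin <- pmax(adj$matrix, t(adj$matrix))
  test_one <- function(i) {
    b <- memb[i, ]
    if (estimator == "reml" && reml_scope == "pathway") {
      members <- which(b != 0)
      nb <- which(colSums(bin[members, , drop = FALSE]) > 0)
      sub <- sort(union(members, nb))
      Lsub <- lapply(wset$Lambda, function(L) L[sub, sub, drop = FALSE])
      Ssub <- lapply(S_list, function(S) S[sub, sub, drop = FALSE])
      vc_p <- reml_estimate(Ssub, Lsub, n_k)
      beta_sub <- lapply(conditions, function(k) {
        # means of the restricted system: Lambda_sub^{-1} ybar_sub
        ybar <- rowMeans(data$values[sub,
                                     data$conditions == k, drop = FALSE])
        solve(Lsub[[k]], ybar)
      })
      names(beta_sub) <- conditions
      pathway_test(beta_sub, Lsub[conditions], vc_p, n_k, b[sub],
                   conditions)
    } else {
      pathway_test(beta[conditions], wset$Lambda[conditions], vc, n_k, b,
                   conditions)
    }
  }
  results <- stage("test", {
    purrr::map_dfr(seq_len(nrow(memb)), test_one) |>
      dplyr::mutate(pathway = rownames(memb), .before = 1L)
  })
  results <- stage("adjust", {
    results$qvalue <- bh_adjust(results$pvalue)
    results$significant <- results$qvalue <= fdr
    results
  })

  log <- list(
    config = list(estimator = estimator, cluster = cluster,
                  max_size = max_size, penalty = penalty,
                  nonedge_penalty = nonedge_penalty,
                  penalty_c = penalty_c, scale = scale,
                  reml_scope = reml_scope, fdr = fdr,
                  conditions = conditions),
    seed = seed,
    algorithms = attr(partition, "algorithms"),
    edge_loss_total = attr(partition, "edge_loss_total"),
    estimator = estimator,
    timing = timing,
    total_elapsed = proc.time()[["elapsed"]] - t0
  )
  structure(list(results = results, variance_components = vc,
                 adjacency = wset, binary_adjacency = adj,
                 partition = partition, pathways = pathways,
                 conditions = conditions, n_k = n_k, fdr = fdr,
                 log = log),
            class = "netgsa_result")
}

#' @export
print.netgsa_result <- function(x, ...) {
  cat("<netgsa_result> ", nrow(x$results), " pathways, contrast ",
      x$conditions[1L], " vs ", x$conditions[2L], ", estimator ",
      x$log$estimator, ", ", sum(x$results$significant),
      " significant at FDR ", x$fdr, "\n", sep = "")
  print(tidy(x), n = 10L)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-pathway enrichment table
#'
#' @param x A `netgsa_result`.
#' @param ... Unused.
#' @return A tibble with one row per pathway: `pathway`, `size`, `stat`,
#'   `df`, `pvalue`, `qvalue`, `significant`, ordered by `qvalue`.
#' @method tidy netgsa_result
#' @export
tidy.netgsa_result <- function(x, ...) {
  dplyr::arrange(x$results, .data$qvalue, .data$pvalue)
}

#' One-row summary of an enrichment run
#'
#' @param x A `netgsa_result`.
#' @param ... Unused.
#' @return One-row tibble: gene and pathway counts, sample sizes,
#'   estimator, variance components (when fitted once for the network),
#'   clustering edge loss, significant-pathway count.
#' @method glance netgsa_result
#' @export
glance.netgsa_result <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$adjacency$partition$gene),
    n_pathways = nrow(x$results),
    n_samples = sum(x$n_k),
    estimator = x$log$estimator,
    sigma2_g = if (is.null(x$variance_components)) NA_real_
               else x$variance_components$sigma2_g,
    sigma2_e = if (is.null(x$variance_components)) NA_real_
               else x$variance_components$sigma2_e,
    edge_loss = x$log$edge_loss_total,
    n_significant = sum(x$results$significant),
    fdr = x$fdr
  )
}

#' Enrichment overview plot
#'
#' Pathways ordered by significance, bar length `-log10(qvalue)`, fill by
#' test-statistic sign, dashed line at the FDR cut-off.
#'
#' @param object A `netgsa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot netgsa_result
#' @export
autoplot.netgsa_result <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      pathway = stats::reorder(.data$pathway, -.data$qvalue),
      direction = ifelse(.data$stat >= 0, "up", "down")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$qvalue, 1e-300)),
                                   y = .data$pathway,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(object$fdr),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "FDR q-value"), y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
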