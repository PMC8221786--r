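#' Describe a power-simulation design
#'
#' Collects the study conditions for the simulation harness: network
#' shape, model variances, sample sizes, pathway layout, dysregulation
#' rule and signal strengths. Defaults are the desk-scale design used
#' throughout the package: 150 genes in two 75-gene components with
#' planted modular structure, 15 pathways, 40 samples per condition and
#' model variances (0.5, 1.0).
#'
#' @param p Total gene count (must equal `sum(component_sizes)`).
#' @param component_sizes Sizes of the connected components.
#' @param module_size Approximate size of the planted modules inside each
#'   component.
#' @param p_within,p_between Edge probabilities inside and between
#'   modules of a component.
#' @param weight_range Magnitude range `[w_lo, w_hi]` of edge weights;
#'   signs are random.
#' @param spectral_target Cap on the spectral radius of each weighted
#'   adjacency (default 0.9, guaranteeing the influence matrix exists).
#' @param n_k Length-2 vector of per-condition sample sizes.
#' @param sigma2_g,sigma2_e Variance components of the generating model.
#' @param n_pathways Number of pathways.
#' @param pathway_size Length-2 range of pathway sizes.
#' @param mu Mean dysregulation signal(s); the study grid is
#'   `c(0.2, 0.3, 0.4)`. Use `0` for a null (no-signal) design.
#' @param framework Dysregulation rule: `"uniform-random"`,
#'   `"betweenness-ranked"` or `"neighborhood-seeded"`.
#' @param fraction Fraction of genes dysregulated (default 0.3).
#' @param perturb_weights Standard deviation of the condition-2 weight
#'   perturbation (0 = shared weights).
#' @param replicates Number of simulated datasets.
#' @param fdr FDR cut-off for counting rejections (default 0.05).
#' @param cluster,max_size Clustering options passed to [run_netgsa()].
#' @param seed Base integer seed.
#' @return A validated list of class `simulation_design`.
#' @export
simulation_design <- function(p = 150L,
                              component_sizes = c(75L, 75L),
                              module_size = 15L,
                              p_within = 0.25, p_between = 0.02,
                              weight_range = c(0.3, 0.7),
                              spectral_target = 0.9,
                              n_k = c(40L, 40L),
                              sigma2_g = 0.5, sigma2_e = 1.0,
                              n_pathways = 15L,
                              pathway_size = c(10L, 40L),
                              mu = c(0.2, 0.3, 0.4),
                              framework = "uniform-random",
                              fraction = 0.3,
                              perturb_weights = 0,
                              replicates = 50L,
                              fdr = 0.05,
                              cluster = TRUE, max_size = 1000L,
                              seed = 1L) {
  if (sum(component_sizes) != p) {
    stop("`component_sizes` must sum to `p`", call. = FALSE)
  }
  if (any(mu < 0)) stop("`mu` must be nonnegative", call. = FALSE)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (any(pathway_size < 1L)) {
    stop("pathway sizes must be >= 1", call. = FALSE)
  }
  if (sigma2_g < 0 || sigma2_e < 0) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  framework <- match.arg(framework, c("uniform-random",
                                      "betweenness-ranked",
                                      "neighborhood-seeded"))
  if (length(n_k) != 2L || any(n_k < 3L)) {
    stop("`n_k` must give two conditions with >= 3 samples each",
         call. = FALSE)
  }
  structure(list(p = p, component_sizes = component_sizes,
                 module_size = module_size, p_within = p_within,
                 p_between = p_between, weight_range = weight_range,
                 spectral_target = spectral_target, n_k = n_k,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 n_pathways = n_pathways, pathway_size = pathway_size,
                 mu = mu, framework = framework, fraction = fraction,
                 perturb_weights = perturb_weights,
                 replicates = replicates, fdr = fdr, cluster = cluster,
                 max_size = max_size, seed = seed),
            class = "simulation_design")
}

#' Generate a random modular network with condition-specific weights
#'
#' Each component is built from planted modules (Erdos-Renyi blocks with
#' dense intra-module and sparse inter-module edges, plus a module
#' spanning chain so the component is connected). Edge weights are drawn
#' uniformly from `[-w_hi, -w_lo] U [w_lo, w_hi]`, symmetrically for the
#' undirected structure, and rescaled so the spectral radius of each
#' condition's weighted adjacency is at most `spectral_target`. Both
#' conditions share the topology; condition 2's weights are perturbed by
#' Gaussian noise of sd `perturb_weights` (0 by default).
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed (defaults to `design$seed`).
#' @return List with `adj` (a `binary_adjacency` of the true support),
#'   `A` (named list of per-condition weighted adjacencies), `Lambda`
#'   (influence matrices), `conditions` (labels `"cond1"`, `"cond2"`).
#' @export
generate_network <- function(design, seed = design$seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(design$p))
    S <- matrix(0, design$p, design$p, dimnames = list(genes, genes))
    offset <- 0L
    for (size in design$component_sizes) {
      idx <- offset + seq_len(size)
      n_mod <- max(1L, round(size / design$module_size))
      module <- rep(seq_len(n_mod), length.out = size)
      module <- sort(module)
      for (i in seq_len(size - 1L)) {
        for (j in (i + 1L):size) {
          pr <- if (module[i] == module[j]) design$p_within
                else design$p_between
          if (stats::runif(1L) < pr) {
            S[idx[i], idx[j]] <- S[idx[j], idx[i]] <- 1
          }
        }
      }
      # spanning chain: consecutive genes of the component, guaranteeing
      # one connected component regardless of the random draws
      for (i in seq_len(size - 1L)) {
        S[idx[i], idx[i + 1L]] <- S[idx[i + 1L], idx[i]] <- 1
      }
      offset <- offset + size
    }
    diag(S) <- 0
    adj <- structure(list(matrix = S, directed = FALSE),
                     class = "binary_adjacency")
    w_lo <- design$weight_range[1L]; w_hi <- design$weight_range[2L]
    draw_weights <- function() {
      W <- matrix(0, design$p, design$p, dimnames = dimnames(S))
      up <- which(upper.tri(S) & S > 0)
      w <- stats::runif(length(up), w_lo, w_hi) *
        sample(c(-1, 1), length(up), replace = TRUE)
      W[up] <- w
      W <- W + t(W)
      W
    }
    rescale <- function(W) {
      if (all(W == 0)) return(W)
      rho <- max(abs(eigen(W, symmetric = TRUE,
                           only.values = TRUE)$values))
      if (rho > design$spectral_target) {
        W <- W * (design$spectral_target / rho)
      }
      W
    }
    A1 <- rescale(draw_weights())
    A2 <- A1
    if (design$perturb_weights > 0) {
      up <- which(upper.tri(S) & S > 0)
      noise <- stats::rnorm(length(up), 0, design$perturb_weights)
      P <- matrix(0, design$p, design$p)
      P[up] <- noise
      A2 <- rescale(A1 + P + t(P))
      A2[S == 0] <- 0
    }
    A <- list(cond1 = A1, cond2 = A2)
    Lambda <- lapply(A, function(a) solve(diag(design$p) - a))
    Lambda <- lapply(Lambda, function(L) {
      dimnames(L) <- dimnames(S); L
    })
    list(adj = adj, A = A, Lambda = Lambda,
         conditions = c("cond1", "cond2"))
  })
}

#' Generate random pathways over the gene universe
#'
#' Pathway sizes are drawn uniformly from `design$pathway_size`; members
#' are sampled without replacement from the universe.
#'
#' @param design A [simulation_design()].
#' @param genes Gene universe (character).
#' @param seed Integer seed.
#' @return A [pathway_set()].
#' @export
generate_pathways <- function(design, genes, seed = design$seed) {
  withr::with_seed(seed, {
    sizes <- sample(seq(design$pathway_size[1L], design$pathway_size[2L]),
                    design$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(genes, min(s, length(genes))))
    names(sets) <- sprintf("pw%02d", seq_along(sets))
    pathway_set(sets, universe = genes)
  })
}

#' Simulate expression data from the latent-variable network model
#'
#' Samples `y_i = Lambda_k (beta_k + gamma_i) + eps_i` with independent
#' mean-zero Gaussian `gamma_i` (variance `sigma2_g`, propagated through
#' the network) and `eps_i` (variance `sigma2_e`).
#'
#' @param net A [generate_network()] result (or any list with `Lambda`
#'   and `conditions`).
#' @param beta Named list of per-condition mean-coefficient vectors
#'   (default all zero).
#' @param sigma2_g,sigma2_e Nonnegative variance components.
#' @param n_k Per-condition sample counts (named or in `net$conditions`
#'   order).
#' @param seed Integer seed.
#' @return An [expression_dataset()].
#' @export
generate_expression <- function(net, beta = NULL, sigma2_g, sigma2_e,
                                n_k, seed) {
  if (sigma2_g < 0 || sigma2_e < 0) {
    stop("variances must be nonnegative", call. = FALSE)
  }
  conds <- net$conditions
  p <- nrow(net$Lambda[[1L]])
  genes <- rownames(net$Lambda[[1L]])
  if (is.null(beta)) {
    beta <- stats::setNames(rep(list(rep(0, p)), length(conds)), conds)
  }
  if (is.null(names(n_k))) names(n_k) <- conds
  withr::with_seed(seed, {
    cols <- list()
    labels <- character()
    for (k in conds) {
      L <- net$Lambda[[k]]
      n <- n_k[[k]]
      gamma <- matrix(stats::rnorm(p * n, 0, sqrt(sigma2_g)), p, n)
      eps <- matrix(stats::rnorm(p * n, 0, sqrt(sigma2_e)), p, n)
      y <- L %*% (beta[[k]] + gamma) + eps
      colnames(y) <- sprintf("%s_s%03d", k, seq_len(n))
      cols[[k]] <- y
      labels <- c(labels,
                  stats::setNames(rep(k, n), colnames(y)))
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    expression_dataset(values, labels)
  })
}

#' Standardize genes and inject a dysregulation signal
#'
#' Each gene is centered and scaled to zero mean and unit variance across
#' all samples; afterwards the mean signal `mu` is added to the
#' dysregulated genes' values in the target condition only.
#'
#' @param data An [expression_dataset()].
#' @param dysregulated Character vector of gene ids (subset of the
#'   universe).
#' @param mu Nonnegative mean signal.
#' @param target Condition label receiving the signal.
#' @return A standardized [expression_dataset()] with the signal added.
#' @export
standardize_and_dysregulate <- function(data, dysregulated, mu, target) {
  if (mu < 0) stop("`mu` must be nonnegative", call. = FALSE)
  stray <- setdiff(dysregulated, data$genes)
  if (length(stray) > 0L) {
    stop("dysregulated gene(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  v <- data$values
  mu_g <- rowMeans(v)
  sd_g <- apply(v, 1L, stats::sd)
  if (any(sd_g == 0)) {
    stop("constant gene(s) cannot be standardized: ",
         paste(utils::head(data$genes[sd_g == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  v <- (v - mu_g) / sd_g
  if (length(dysregulated) > 0L && mu > 0) {
    if (!target %in% data$conditions) {
      stop("target condition '", target, "' not present", call. = FALSE)
    }
    v[dysregulated, data$conditions == target] <-
      v[dysregulated, data$conditions == target] + mu
  }
  expression_dataset(v, data$conditions)
}

#' Select dysregulated genes under a seedable framework
#'
#' Three concrete frameworks: `"uniform-random"` samples genes uniformly;
#' `"betweenness-ranked"` takes the top fraction by betweenness
#' centrality of the 0-1 network (ties broken by gene id);
#' `"neighborhood-seeded"` grows sets along edges from random seed genes
#' until the target count is reached.
#'
#' @param adj A `binary_adjacency`.
#' @param framework One of the three framework names.
#' @param fraction Fraction of genes to dysregulate, in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of gene ids (sorted).
#' @export
select_dysregulated <- function(adj, framework, fraction, seed) {
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  framework <- match.arg(framework, c("uniform-random",
                                      "betweenness-ranked",
                                      "neighborhood-seeded"))
  genes <- rownames(adj$matrix)
  n_target <- ceiling(fraction * length(genes))
  withr::with_seed(seed, {
    chosen <- switch(
      framework,
      "uniform-random" = sample(genes, n_target),
      "betweenness-ranked" = {
        g <- as_igraph(adj, undirected_view = TRUE)
        bw <- igraph::betweenness(g)
        genes[order(-bw, genes)][seq_len(n_target)]
      },
      "neighborhood-seeded" = {
        m <- pmax(adj$matrix, t(adj$matrix))
        chosen <- character()
        frontier <- character()
        while (length(chosen) < n_target) {
          if (length(frontier) == 0L) {
            frontier <- sample(setdiff(genes, chosen), 1L)
          }
          nxt <- frontier[1L]
          frontier <- frontier[-1L]
          if (nxt %in% chosen) next
          chosen <- c(chosen, nxt)
          nb <- genes[m[nxt, ] > 0]
          frontier <- c(frontier, setdiff(nb, chosen))
        }
        chosen[seq_len(n_target)]
      })
    sort(chosen)
  })
}

group_by_dysregulation <- function(n_dys) {
  cut(n_dys, breaks = c(-Inf, 0, 5, 10, Inf),
      labels = c("None", "(0,5]", "(5,10]", ">10"))
}

#' Run a power and type-I-error simulation study
#'
#' For each replicate and each signal level `mu`: generate a network and
#' pathways, simulate null expression data from the latent-variable
#' model, standardize and inject the dysregulation signal into condition
#' 2, run the full enrichment pipeline, and record each pathway's
#' rejection at the FDR cut-off. Pathways are grouped by their number of
#' dysregulated member genes (None, (0,5], (5,10], >10); the None group
#' estimates type-I error, the others power. Common random numbers are
#' used across `mu` levels (the same data and dysregulated set underlie
#' each replicate's signal levels).
#'
#' @param design A [simulation_design()].
#' @param estimator Passed to [run_netgsa()] (default `"rehe"`).
#' @param keep_details Also return the per-pathway replicate-level table.
#' @return A tibble of class `power_table` with columns `group`, `mu`,
#'   `power`, `se`, `n_pathway_instances`; when `keep_details = TRUE` the
#'   attribute `"details"` carries the instance-level table.
#' @export
run_power_study <- function(design, estimator = "rehe",
                            keep_details = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  details <- list()
  for (r in seq_len(design$replicates)) {
    rep_seed <- design$seed + 1009L * r
    net <- generate_network(design, seed = rep_seed)
    pws <- generate_pathways(design, rownames(net$adj$matrix),
                             seed = rep_seed + 1L)
    raw <- generate_expression(net, sigma2_g = design$sigma2_g,
                               sigma2_e = design$sigma2_e,
                               n_k = design$n_k, seed = rep_seed + 2L)
    dys_all <- select_dysregulated(net$adj, design$framework,
                                   design$fraction, seed = rep_seed + 3L)
    edges <- adjacency_to_edges(net$adj)
    for (mu in design$mu) {
      dys <- if (mu == 0) character() else dys_all
      dat <- standardize_and_dysregulate(raw, dys, mu, target = "cond2")
      fit <- run_netgsa(dat, edges, pws, estimator = estimator,
                        cluster = design$cluster,
                        max_size = design$max_size, fdr = design$fdr,
                        seed = rep_seed)
      memb <- pws$membership
      n_dys <- as.integer(memb %*% as.numeric(colnames(memb) %in% dys))
      res <- fit$results
      details[[length(details) + 1L]] <- tibble::tibble(
        replicate = r, mu = mu, pathway = res$pathway,
        size = res$size, n_dysregulated = n_dys[match(res$pathway,
                                                      rownames(memb))],
        rejected = res$significant
      )
    }
  }
  details <- dplyr::bind_rows(details)
  details$group <- group_by_dysregulation(details$n_dysregulated)
  out <- details |>
    dplyr::group_by(.data$group, .data$mu) |>
    dplyr::summarise(
      power = mean(.data$rejected),
      se = stats::sd(.data$rejected) / sqrt(dplyr::n()),
      n_pathway_instances = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "design") <- design
  if (keep_details) attr(out, "details") <- details
  class(out) <- c("power_table", class(tibble::tibble()))
  out
}

#' Convert a binary adjacency back to an edge list
#'
#' @param adj A `binary_adjacency`.
#' @return An [edge_list()] (canonical order for undirected edges).
#' @export
adjacency_to_edges <- function(adj) {
  m <- adj$matrix
  if (adj$directed) {
    idx <- which(m > 0, arr.ind = TRUE)
  } else {
    idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  }
  if (nrow(idx) == 0L) return(edge_list(character(), character()))
  edge_list(rownames(m)[idx[, 1L]], colnames(m)[idx[, 2L]],
            directed = adj$directed)
}

#' Power-table plot
#'
#' Mean power (with +/- 1 SE ribbons) against the dysregulation signal,
#' one line per dysregulated-gene group.
#'
#' @param object A `power_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_table
#' @export
autoplot.power_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mu, y = .data$power,
                               colour = .data$group,
                               group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$power - .data$se, 0),
      ymax = pmin(.data$power + .data$se, 1))) +
    ggplot2::labs(x = "mean dysregulation signal", y = "power",
                  colour = "dysregulated genes") +
    ggplot2::theme_minimal()
}
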