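#' Build the 0-1 adjacency matrix from an edge list
#'
#' @param edges An [edge_list()]; endpoints outside `universe` must already
#'   have been dropped (see [restrict_to_universe()]).
#' @param universe Character vector giving the canonical gene order.
#' @return An object of class `binary_adjacency`: list with `matrix` (0/1,
#'   zero diagonal, dimnames = universe) and `directed` (logical). For
#'   undirected edges both (i, j) and (j, i) are set; a directed edge a->b
#'   sets only (a, b).
#' @export
build_binary_adjacency <- function(edges, universe) {
  universe <- as.character(universe)
  p <- length(universe)
  A <- matrix(0, p, p, dimnames = list(universe, universe))
  directed <- FALSE
  if (!is.null(edges) && nrow(edges) > 0L) {
    stray <- setdiff(unique(c(edges$src, edges$dst)), universe)
    if (length(stray) > 0L) {
      stop("edge endpoints outside the universe: ",
           paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
    }
    directed <- any(edges$directed)
    if (directed && !all(edges$directed)) {
      stop("edge list mixes directed and undirected edges", call. = FALSE)
    }
    i <- match(edges$src, universe)
    j <- match(edges$dst, universe)
    A[cbind(i, j)] <- 1
    if (!directed) A[cbind(j, i)] <- 1
  }
  diag(A) <- 0
  structure(list(matrix = A, directed = directed),
            class = "binary_adjacency")
}

#' @export
print.binary_adjacency <- function(x, ...) {
  n_edges <- if (x$directed) sum(x$matrix) else sum(x$matrix) / 2
  cat("<binary_adjacency> ", nrow(x$matrix), " genes, ", n_edges,
      if (x$directed) " directed" else " undirected", " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(adj, undirected_view = FALSE) {
  m <- adj$matrix
  directed <- adj$directed && !undirected_view
  if (adj$directed && undirected_view) m <- pmax(m, t(m))
  igraph::graph_from_adjacency_matrix(
    m, mode = if (directed) "directed" else "undirected")
}

#' Connected components of a binary adjacency
#'
#' Weak connectivity is used for directed graphs. Components are returned
#' ordered by decreasing size, ties broken by the lexicographically
#' smallest member, so the ordering is deterministic.
#'
#' @param adj A [build_binary_adjacency()] result.
#' @return List of character vectors of gene ids (each sorted).
#' @export
connected_components <- function(adj) {
  g <- as_igraph(adj)
  comp <- igraph::components(g, mode = "weak")
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-lengths(sets), vapply(sets, `[[`, "", 1L))
  unname(sets[ord])
}

#' Count edges lost by restricting a network to within-cluster edges
#'
#' Edge loss is the number of distinct edges of the 0-1 adjacency whose
#' endpoints fall in different clusters (unweighted count; for directed
#' graphs a reciprocal pair i<->j counts as one distinct edge).
#'
#' @param adj A `binary_adjacency`.
#' @param partition Named vector (gene -> cluster id) covering all nodes.
#' @return Integer count of cross-cluster edges.
#' @export
edge_loss <- function(adj, partition) {
  genes <- rownames(adj$matrix)
  missing <- setdiff(genes, names(partition))
  if (length(missing) > 0L) {
    stop("node(s) missing from partition: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  m <- pmax(adj$matrix, t(adj$matrix))
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  cl <- partition[genes]
  sum(cl[idx[, 1L]] != cl[idx[, 2L]])
}

# The six candidate community-detection algorithms, in the fixed
# tie-breaking priority order.
cluster_algorithms <- function() {
  c("walktrap", "leading_eigen", "fast_greedy",
    "label_prop", "infomap", "louvain")
}

run_community_algorithm <- function(graph, algorithm, seed) {
  # label_prop, infomap, louvain are stochastic: fix the RNG per call so
  # partitions are reproducible across runs
  fit <- withr::with_seed(seed, switch(
    algorithm,
    walktrap = igraph::cluster_walktrap(graph),
    leading_eigen = suppressWarnings(igraph::cluster_leading_eigen(graph)),
    fast_greedy = igraph::cluster_fast_greedy(graph),
    label_prop = igraph::cluster_label_prop(graph),
    infomap = igraph::cluster_infomap(graph),
    louvain = igraph::cluster_louvain(graph),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  ))
  stats::setNames(igraph::membership(fit), igraph::V(graph)$name)
}

#' Partition one connected component under the size cap
#'
#' Components at or below `max_size` are kept whole (label "none").
#' Oversized components are clustered by six community-detection
#' algorithms (walktrap, leading eigenvector, fast greedy, label
#' propagation, infomap, louvain) on the undirected view; candidates whose
#' largest cluster still exceeds `max_size` are discarded, and among the
#' survivors the partition with the smallest edge loss is chosen (ties
#' broken by the fixed algorithm order above). If every candidate is
#' discarded, the minimum-edge-loss candidate is refined by recursive
#' re-clustering of its oversized clusters (up to 3 rounds); if clusters
#' remain oversized the component is kept whole with a warning.
#'
#' @param adj A `binary_adjacency` (full network).
#' @param component Character vector of member genes (a connected set).
#' @param max_size Maximum allowed cluster size (default 1000).
#' @param seed Integer seed for the stochastic algorithms.
#' @param .round Internal recursion counter.
#' @return List with `membership` (named gene -> local cluster id),
#'   `algorithm` (label), `edge_loss` (within this component).
#' @export
cluster_component <- function(adj, component, max_size = 1000L, seed = 1L,
                              .round = 0L) {
  sub <- structure(list(
    matrix = adj$matrix[component, component, drop = FALSE],
    directed = adj$directed), class = "binary_adjacency")
  if (length(component) <= max_size) {
    return(list(membership = stats::setNames(rep(1L, length(component)),
                                             component),
                algorithm = "none", edge_loss = 0L))
  }
  g <- as_igraph(sub, undirected_view = TRUE)
  algos <- cluster_algorithms()
  candidates <- list()
  for (a in algos) {
    memb <- tryCatch(run_community_algorithm(g, a, seed),
                     error = function(e) NULL)
    if (is.null(memb)) next
    candidates[[a]] <- list(
      membership = memb,
      max_cluster = max(table(memb)),
      loss = edge_loss(sub, memb)
    )
  }
  if (length(candidates) == 0L) {
    warning("no community-detection algorithm succeeded on a component of ",
            length(component), " genes; keeping it whole", call. = FALSE)
    return(list(membership = stats::setNames(rep(1L, length(component)),
                                             component),
                algorithm = "none", edge_loss = 0L))
  }
  losses <- vapply(candidates, `[[`, 0, "loss")
  ok <- vapply(candidates, function(c) c$max_cluster <= max_size, TRUE)
  if (any(ok)) {
    surv <- names(candidates)[ok]
    chosen <- surv[which.min(losses[surv])]  # which.min: first = priority order
    return(list(membership = candidates[[chosen]]$membership,
                algorithm = chosen,
                edge_loss = candidates[[chosen]]$loss))
  }
  # all candidates discarded: refine the min-loss candidate recursively
  if (.round >= 3L) {
    warning("component of ", length(component), " genes could not be split ",
            "below max_size = ", max_size, " after 3 rounds; keeping whole",
            call. = FALSE)
    return(list(membership = stats::setNames(rep(1L, length(component)),
                                             component),
                algorithm = "none", edge_loss = 0L))
  }
  chosen <- names(candidates)[which.min(losses)]
  memb <- candidates[[chosen]]$membership
  loss <- candidates[[chosen]]$loss
  next_id <- max(memb)
  for (cl in unique(memb)) {
    members <- names(memb)[memb == cl]
    if (length(members) <= max_size) next
    # clusters of a connected component may themselves be disconnected;
    # recurse over their connected pieces
    piece_adj <- structure(list(
      matrix = adj$matrix[members, members, drop = FALSE],
      directed = adj$directed), class = "binary_adjacency")
    for (piece in connected_components(piece_adj)) {
      refit <- cluster_component(adj, piece, max_size = max_size,
                                 seed = seed, .round = .round + 1L)
      memb[piece] <- refit$membership[piece] + next_id
      next_id <- next_id + max(refit$membership)
      loss <- loss + refit$edge_loss
    }
  }
  # relabel to consecutive ids
  memb <- stats::setNames(match(memb, unique(memb)), names(memb))
  list(membership = memb, algorithm = paste0(chosen, "+recursive"),
       edge_loss = loss)
}

#' Cluster the whole network into a block-diagonal partition
#'
#' Finds connected components, splits oversized ones via
#' [cluster_component()], and assembles a global partition whose clusters
#' never span two components. Ordering genes by cluster id makes the
#' within-cluster adjacency block diagonal.
#'
#' @param adj A `binary_adjacency`, or `NULL` to build it from `edges`.
#' @param edges Optional [edge_list()] (used when `adj` is `NULL`).
#' @param universe Gene universe (required with `edges`).
#' @param max_size Maximum cluster size before a component is split
#'   (default 1000, matching the threshold used on gene-scale networks).
#' @param seed Integer seed for the stochastic community algorithms.
#' @return A tibble of class `cluster_partition` with columns `gene`,
#'   `component`, `cluster` (global ids, block order), and attributes
#'   `algorithms` (label per component), `edge_loss_total`, `max_size`.
#' @export
cluster_network <- function(adj = NULL, edges = NULL, universe = NULL,
                            max_size = 1000L, seed = 1L) {
  if (is.null(adj)) {
    if (is.null(universe)) stop("need `universe` with `edges`", call. = FALSE)
    adj <- build_binary_adjacency(edges, universe)
  }
  comps <- connected_components(adj)
  rows <- list()
  algorithms <- character(length(comps))
  loss_total <- 0L
  next_cluster <- 0L
  for (ci in seq_along(comps)) {
    fit <- cluster_component(adj, comps[[ci]], max_size = max_size,
                             seed = seed)
    algorithms[ci] <- fit$algorithm
    loss_total <- loss_total + fit$edge_loss
    # order clusters within the component by local id for determinism
    ord <- order(fit$membership, names(fit$membership))
    rows[[ci]] <- tibble::tibble(
      gene = names(fit$membership)[ord],
      component = ci,
      cluster = next_cluster + fit$membership[ord]
    )
    next_cluster <- next_cluster + max(fit$membership)
  }
  out <- dplyr::bind_rows(rows)
  stray <- setdiff(rownames(adj$matrix), out$gene)
  if (length(stray) > 0L || anyDuplicated(out$gene)) {
    stop("partition does not cover the universe exactly", call. = FALSE)
  }
  attr(out, "algorithms") <- algorithms
  attr(out, "edge_loss_total") <- loss_total
  attr(out, "max_size") <- max_size
  class(out) <- c("cluster_partition", class(tibble::tibble()))
  out
}

#' Trivial one-cluster-per-component partition (clustering off)
#'
#' @param adj A `binary_adjacency`.
#' @return A `cluster_partition` where every connected component is a
#'   single cluster.
#' @export
trivial_partition <- function(adj) {
  cluster_network(adj, max_size = nrow(adj$matrix))
}

partition_clusters <- function(partition) {
  split(partition$gene, partition$cluster)
}

#' Permute a matrix into the block order of a partition
#'
#' @param m Matrix with gene dimnames.
#' @param partition A `cluster_partition`.
#' @return `m` with rows and columns ordered by cluster id (block
#'   diagonal sparsity for within-cluster matrices).
#' @export
block_permute <- function(m, partition) {
  ord <- partition$gene
  m[ord, ord, drop = FALSE]
}
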