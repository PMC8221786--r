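#' Pathway-level graph of enrichment results
#'
#' Builds a graph whose nodes are pathways, annotated with size, test
#' statistic, p-value, FDR q-value and a significance flag, and whose
#' edges connect two pathways whenever at least one gene of one pathway
#' has a network edge to at least one gene of the other. Each edge
#' carries `cross_edge_count`, the number of distinct gene-gene edges
#' between the two member sets.
#'
#' @param results A `netgsa_result` or its [tidy()] tibble (columns
#'   `pathway`, `size`, `stat`, `pvalue`, `qvalue`).
#' @param pathways A [pathway_set()] covering all result pathways.
#' @param adj A `binary_adjacency` over the gene universe (taken from the
#'   result when `results` is a `netgsa_result`).
#' @param fdr_cut Significance cut-off for the node flag (default: the
#'   run's FDR level, else 0.05).
#' @return An igraph object of class `pathway_graph` with typed node and
#'   edge attributes.
#' @export
build_pathway_graph <- function(results, pathways = NULL, adj = NULL,
                                fdr_cut = NULL) {
  if (inherits(results, "netgsa_result")) {
    if (is.null(pathways)) pathways <- results$pathways
    if (is.null(adj)) adj <- results$binary_adjacency
    if (is.null(fdr_cut)) fdr_cut <- results$fdr
    results <- results$results
  }
  if (is.null(fdr_cut)) fdr_cut <- 0.05
  stopifnot(inherits(pathways, "pathway_set"),
            inherits(adj, "binary_adjacency"))
  missing_pw <- setdiff(results$pathway, rownames(pathways$membership))
  if (length(missing_pw) > 0L) {
    stop("pathway(s) in results missing from the membership: ",
         paste(utils::head(missing_pw, 5L), collapse = ", "),
         call. = FALSE)
  }
  memb <- pathways$membership[results$pathway, , drop = FALSE] > 0
  m <- pmax(adj$matrix, t(adj$matrix))
  eidx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  n_pw <- nrow(results)
  from <- integer(); to <- integer(); cnt <- integer()
  if (n_pw >= 2L && nrow(eidx) > 0L) {
    for (q in seq_len(n_pw - 1L)) {
      aq <- memb[q, eidx[, 1L]]; bq <- memb[q, eidx[, 2L]]
      for (r in (q + 1L):n_pw) {
        ar <- memb[r, eidx[, 1L]]; br <- memb[r, eidx[, 2L]]
        k <- sum((aq & br) | (bq & ar))
        if (k > 0L) {
          from <- c(from, q); to <- c(to, r); cnt <- c(cnt, k)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n_pw, directed = FALSE)
  igraph::V(g)$name <- results$pathway
  igraph::V(g)$size <- as.numeric(results$size)
  igraph::V(g)$stat <- as.numeric(results$stat)
  igraph::V(g)$pvalue <- as.numeric(results$pvalue)
  igraph::V(g)$qvalue <- as.numeric(results$qvalue)
  igraph::V(g)$significant <- results$qvalue <= fdr_cut
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$cross_edge_count <- as.numeric(cnt)
  }
  class(g) <- c("pathway_graph", class(g))
  g
}

#' Induced subgraph of significant pathways
#'
#' @param graph A [build_pathway_graph()] result.
#' @return The induced `pathway_graph` on nodes flagged significant.
#' @export
subgraph_significant <- function(graph) {
  keep <- which(igraph::V(graph)$significant)
  sub <- igraph::induced_subgraph(graph, keep)
  class(sub) <- c("pathway_graph", class(sub))
  sub
}

#' Export a pathway graph to GraphML
#'
#' Writes standard GraphML with all node and edge attributes typed
#' (numeric attributes as doubles, flags as booleans), so the file
#' round-trips through any generic GraphML reader.
#'
#' @param graph A `pathway_graph` (any igraph object works).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#'
#' @param path GraphML file path.
#' @return An igraph object.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Tidy a pathway graph into a node table
#'
#' @param x A `pathway_graph`.
#' @param ... Unused.
#' @return Tibble of node attributes, one row per pathway.
#' @method tidy pathway_graph
#' @export
tidy.pathway_graph <- function(x, ...) {
  tibble::tibble(
    pathway = igraph::V(x)$name,
    size = igraph::V(x)$size,
    stat = igraph::V(x)$stat,
    pvalue = igraph::V(x)$pvalue,
    qvalue = igraph::V(x)$qvalue,
    significant = igraph::V(x)$significant
  )
}

#' Plot a pathway graph
#'
#' Nodes placed by Fruchterman-Reingold layout, sized by member count,
#' coloured by `-log10(qvalue)`; significant pathways get a solid
#' outline.
#'
#' @param object A `pathway_graph`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_graph
#' @export
autoplot.pathway_graph <- function(object, seed = 1L, ...) {
  xy <- withr::with_seed(seed, igraph::layout_with_fr(object))
  nodes <- tidy(object)
  nodes$x <- xy[, 1L]; nodes$y <- xy[, 2L]
  el <- igraph::as_edgelist(object, names = FALSE)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el) > 0L) {
    segs <- tibble::tibble(x = xy[el[, 1L], 1L], y = xy[el[, 1L], 2L],
                           xend = xy[el[, 2L], 1L],
                           yend = xy[el[, 2L], 2L])
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey70")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(
      size = .data$size,
      colour = -log10(pmax(.data$qvalue, 1e-300)),
      shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 19)) +
    ggplot2::labs(colour = expression(-log[10] ~ "q"), size = "genes",
                  shape = "significant") +
    ggplot2::theme_void()
}
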