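#' Edge lists of known gene-gene interactions
#'
#' An edge list is a tibble with columns `src`, `dst`, `directed` (logical)
#' and `origin` (free-text database tag), one row per interaction. It stands
#' in for an export from curated interaction databases (KEGG, Reactome, ...)
#' and is the 0-1 structural knowledge that constrains weighted-adjacency
#' estimation. Undirected edges are stored once, with endpoints in canonical
#' (lexicographically smallest first) order; directedness is a per-edge flag.
#'
#' @param src,dst Character vectors of gene identifiers.
#' @param directed Logical vector (recycled) flagging directed edges.
#' @param origin Character vector (recycled) naming the source database.
#' @return A tibble of class `edge_list` with columns `src`, `dst`,
#'   `directed`, `origin`. Self-loops are dropped (with a message giving the
#'   count) and duplicate `(src, dst, directed)` triples are removed.
#' @examples
#' edge_list(c("g1", "g2"), c("g2", "g3"))
#' @export
edge_list <- function(src, dst, directed = FALSE, origin = NA_character_) {
  src <- as.character(src)
  dst <- as.character(dst)
  if (length(src) != length(dst)) {
    stop("`src` and `dst` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(src)) || any(!nzchar(dst)) || anyNA(src) || anyNA(dst)) {
    stop("gene identifiers must be non-empty strings", call. = FALSE)
  }
  el <- tibble::tibble(
    src = src, dst = dst,
    directed = rep_len(as.logical(directed), length(src)),
    origin = rep_len(as.character(origin), length(src))
  )
  n_loop <- sum(el$src == el$dst)
  if (n_loop > 0) {
    message("dropping ", n_loop, " self-loop(s)")
    el <- el[el$src != el$dst, , drop = FALSE]
  }
  # canonicalize undirected edges so (a,b) and (b,a) deduplicate together
  flip <- !el$directed & el$src > el$dst
  tmp <- el$src[flip]
  el$src[flip] <- el$dst[flip]
  el$dst[flip] <- tmp
  el <- dplyr::distinct(el, .data$src, .data$dst, .data$directed, .keep_all = TRUE)
  class(el) <- c("edge_list", class(tibble::tibble()))
  el
}

#' Read a gene-gene interaction edge list from a TSV file
#'
#' Expected layout: `src<TAB>dst[<TAB>directed][<TAB>origin]`, with or
#' without a header row (a header is detected when the third field of the
#' first line is not 0/1 and the first two fields are literally "src"/"dst"
#' or similar). `directed` must be 0 or 1 when present.
#'
#' @param path Path to the tab-separated file.
#' @param directed_default Directedness assigned to rows lacking a
#'   `directed` column.
#' @param coerce_undirected If the file mixes directed and undirected edges,
#'   reject it unless this is `TRUE`, in which case all edges are coerced to
#'   undirected. Mixed networks flow to different estimators, so silent
#'   mixing is an error.
#' @return An [edge_list()].
#' @export
read_edge_list <- function(path, directed_default = FALSE,
                           coerce_undirected = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty edge-list file: ", path, call. = FALSE)
    return(edge_list(character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  has_header <- identical(tolower(first[1:2]), c("src", "dst"))
  if (has_header) {
    fields <- fields[-1L]
    lines <- lines[-1L]
  }
  if (length(fields) == 0L) {
    warning("edge-list file contains only a header: ", path, call. = FALSE)
    return(edge_list(character(), character()))
  }
  n_fields <- lengths(fields)
  bad <- which(n_fields < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list row at line ", bad[1L] + has_header,
         ": fewer than 2 tab-separated fields", call. = FALSE)
  }
  src <- vapply(fields, `[[`, "", 1L)
  dst <- vapply(fields, `[[`, "", 2L)
  dir_chr <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_, "")
  origin <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  directed <- rep(directed_default, length(src))
  have_dir <- !is.na(dir_chr) & nzchar(dir_chr)
  if (any(have_dir)) {
    ok <- dir_chr[have_dir] %in% c("0", "1")
    if (!all(ok)) {
      stop("malformed edge-list row at line ",
           which(have_dir)[!ok][1L] + has_header,
           ": `directed` must be 0 or 1", call. = FALSE)
    }
    directed[have_dir] <- dir_chr[have_dir] == "1"
  }
  if (length(unique(directed)) > 1L) {
    if (coerce_undirected) {
      directed[] <- FALSE
    } else {
      stop("edge list mixes directed and undirected edges; ",
           "set `coerce_undirected = TRUE` to coerce all to undirected",
           call. = FALSE)
    }
  }
  edge_list(src, dst, directed = directed, origin = origin)
}

#' Write an edge list to TSV
#'
#' Inverse of [read_edge_list()]: writing then reading reproduces the same
#' record set.
#'
#' @param edges An [edge_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "edge_list"))
  out <- data.frame(src = edges$src, dst = edges$dst,
                    directed = as.integer(edges$directed),
                    origin = ifelse(is.na(edges$origin), "", edges$origin))
  utils::write.table(rbind(c("src", "dst", "directed", "origin"), as.matrix(out)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a pathway set from a membership list or matrix
#'
#' A pathway set couples pathway labels with a pathway-by-gene 0/1
#' membership matrix (rows are the indicator vectors used as test
#' contrasts). Pathways with no member in the gene universe are dropped
#' with a warning.
#'
#' @param x Either a named list of character vectors of member genes, or a
#'   0/1 matrix with pathway rows and gene columns (dimnames required).
#' @param universe Optional character vector; membership is restricted to
#'   this gene universe.
#' @return An object of class `pathway_set`: a list with elements
#'   `membership` (0/1 matrix, pathway rows) and `names`.
#' @export
pathway_set <- function(x, universe = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("membership matrix needs pathway rownames and gene colnames",
           call. = FALSE)
    }
    if (!all(x %in% c(0, 1))) {
      stop("membership entries must be 0 or 1", call. = FALSE)
    }
    memb <- x
    storage.mode(memb) <- "double"
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("pathway list must be named", call. = FALSE)
    }
    genes <- sort(unique(unlist(x, use.names = FALSE)))
    memb <- matrix(0, nrow = length(x), ncol = length(genes),
                   dimnames = list(names(x), genes))
    for (i in seq_along(x)) memb[i, unique(x[[i]])] <- 1
  } else {
    stop("`x` must be a named list or a 0/1 matrix", call. = FALSE)
  }
  if (!is.null(universe)) {
    universe <- as.character(universe)
    keep <- intersect(colnames(memb), universe)
    dropped_genes <- setdiff(colnames(memb), universe)
    if (length(dropped_genes) > 0L) {
      message("dropping ", length(dropped_genes),
              " pathway gene(s) absent from the universe")
    }
    full <- matrix(0, nrow = nrow(memb), ncol = length(universe),
                   dimnames = list(rownames(memb), universe))
    full[, keep] <- memb[, keep, drop = FALSE]
    memb <- full
  }
  empty <- rowSums(memb) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " pathway(s) with no member gene in the universe: ",
            paste(utils::head(rownames(memb)[empty], 5L), collapse = ", "),
            call. = FALSE)
    memb <- memb[!empty, , drop = FALSE]
  }
  structure(list(membership = memb, names = rownames(memb)),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("<pathway_set> ", nrow(x$membership), " pathways over ",
      ncol(x$membership), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.pathway_set <- function(x) nrow(x$membership)

#' Tidy a pathway set into a long membership tibble
#'
#' @param x A `pathway_set`.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `gene`.
#' @method tidy pathway_set
#' @export
tidy.pathway_set <- function(x, ...) {
  idx <- which(x$membership == 1, arr.ind = TRUE)
  tibble::tibble(
    pathway = rownames(x$membership)[idx[, 1L]],
    gene = colnames(x$membership)[idx[, 2L]]
  ) |> dplyr::arrange(.data$pathway, .data$gene)
}

#' Read pathways from a GMT file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Membership is
#' restricted to `universe` when given; pathways losing all members are
#' dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param universe Optional gene universe (character vector).
#' @return A [pathway_set()].
#' @export
read_pathways_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line ", short[1L],
         ": need name, description and at least one member", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway names in GMT file", call. = FALSE)
  }
  pathway_set(sets, universe = universe)
}

#' Write a pathway set to GMT
#'
#' @param pathways A [pathway_set()].
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults
#'   to the pathway names).
#' @return `path`, invisibly.
#' @export
write_pathways_gmt <- function(pathways, path, descriptions = NULL) {
  stopifnot(inherits(pathways, "pathway_set"))
  if (is.null(descriptions)) descriptions <- pathways$names
  lines <- vapply(seq_along(pathways$names), function(i) {
    members <- colnames(pathways$membership)[pathways$membership[i, ] == 1]
    paste(c(pathways$names[i], descriptions[i], members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 0/1 pathway membership matrix from CSV
#'
#' Alternative to GMT: a CSV with pathway rows (first column = pathway
#' name, remaining columns = genes) and 0/1 entries.
#'
#' @inheritParams read_pathways_gmt
#' @return A [pathway_set()].
#' @export
read_pathway_matrix <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  pathway_set(as.matrix(df), universe = universe)
}

#' Construct an expression dataset
#'
#' The container for gene-by-sample expression with a sample-to-condition
#' map. The row order of `values` is the single canonical gene order shared
#' by every downstream matrix (binary adjacency, weighted adjacency,
#' influence matrix, mean coefficients).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames. No missing values.
#' @param conditions Named character vector mapping sample id to condition
#'   label, or a data frame with columns `sample`, `condition`.
#' @return An object of class `expression_dataset`: list with `values`,
#'   `genes`, `samples`, `conditions` (named character vector).
#' @export
expression_dataset <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(values)[idx[1L]],
         "', sample '", colnames(values)[idx[2L]], "'", call. = FALSE)
  }
  if (is.data.frame(conditions)) {
    conditions <- stats::setNames(as.character(conditions$condition),
                                  as.character(conditions$sample))
  }
  missing_samp <- setdiff(colnames(values), names(conditions))
  if (length(missing_samp) > 0L) {
    stop("sample(s) missing from the condition map: ",
         paste(utils::head(missing_samp, 5L), collapse = ", "), call. = FALSE)
  }
  conditions <- conditions[colnames(values)]
  tab <- table(conditions)
  if (length(tab) < 2L) {
    stop("need >= 2 distinct conditions, got ", length(tab), call. = FALSE)
  }
  if (any(tab < 3L)) {
    stop("every condition needs >= 3 samples; too few in: ",
         paste(names(tab)[tab < 3L], collapse = ", "), call. = FALSE)
  }
  structure(list(values = values,
                 genes = rownames(values),
                 samples = colnames(values),
                 conditions = conditions),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$conditions)
  cat("<expression_dataset> ", length(x$genes), " genes x ",
      length(x$samples), " samples; conditions: ",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and condition map from delimited files
#'
#' @param path Delimited matrix (CSV or TSV, sniffed from the header line):
#'   first column gene id, header row of sample ids.
#' @param condition_map Two-column TSV `sample<TAB>condition` (header
#'   optional).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, condition_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(condition_map)) {
    stop("file not found: ", condition_map, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, row.names = 1L,
                          colClasses = NA, comment.char = "")
  values <- as.matrix(df)
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(values),
                                               nrow(values)))) &
                   !is.na(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("non-numeric expression value at gene '",
           rownames(values)[bad[1L, 1L]], "', sample '",
           colnames(values)[bad[1L, 2L]], "'", call. = FALSE)
    }
    storage.mode(values) <- "double"
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing expression value at gene '", rownames(values)[idx[1L]],
         "', sample '", colnames(values)[idx[2L]], "'", call. = FALSE)
  }
  cm <- utils::read.table(condition_map, sep = "\t", header = FALSE,
                          col.names = c("sample", "condition"),
                          colClasses = "character")
  if (identical(tolower(cm$sample[1L]), "sample")) cm <- cm[-1L, , drop = FALSE]
  expression_dataset(values, stats::setNames(cm$condition, cm$sample))
}

#' Restrict edges and pathways to the expression gene universe
#'
#' The expression matrix defines the gene universe: genes present in the
#' edge list or pathways but absent from the expression data are dropped
#' (with a message listing how many), while expression genes with no known
#' interaction are retained as isolated network nodes.
#'
#' @param edges An [edge_list()] or `NULL`.
#' @param pathways A [pathway_set()] or `NULL`.
#' @param universe Character vector of expression gene ids (canonical order).
#' @return List with elements `edges`, `pathways`, both restricted.
#' @export
restrict_to_universe <- function(edges, pathways, universe) {
  if (!is.null(edges)) {
    keep <- edges$src %in% universe & edges$dst %in% universe
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      lost <- setdiff(unique(c(edges$src, edges$dst)), universe)
      message("dropping ", n_drop, " edge(s) touching ", length(lost),
              " gene(s) absent from the expression universe")
    }
    edges <- edges[keep, , drop = FALSE]
    class(edges) <- c("edge_list", class(tibble::tibble()))
  }
  if (!is.null(pathways)) {
    pathways <- pathway_set(pathways$membership, universe = universe)
  }
  list(edges = edges, pathways = pathways)
}
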