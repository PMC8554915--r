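#' Construct a graph from an edge index matrix
#'
#' Constructor for the package's undirected, unweighted graph type.
#' Edges are stored as a two-column integer matrix of node indices with
#' \code{i < j} per row, deduplicated, with self-pairs removed by the callers
#' that admit them.
#'
#' @param node_ids character vector of external node identifiers, in node order.
#' @param edges two-column integer matrix of node indices (any orientation;
#'   canonicalised internally).
#' @return An object of class \code{gfae_graph} with fields \code{node_ids},
#'   \code{edges} (m x 2 integer matrix, \code{i < j}, sorted), and
#'   \code{n_nodes}.
#' @export
new_graph <- function(node_ids, edges) {
  node_ids <- as.character(node_ids)
  n <- length(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node identifiers")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-edges not allowed in graph")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  storage.mode(edges) <- "integer"
  structure(list(node_ids = node_ids, edges = edges, n_nodes = n),
            class = "gfae_graph")
}

#' @export
print.gfae_graph <- function(x, ...) {
  cat(sprintf("<gfae_graph> %d nodes, %d undirected edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a graph
#' @param g a \code{gfae_graph}.
#' @return integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Read an undirected edge list from a delimited text file
#'
#' Each non-comment line names one interaction by a pair of node identifiers
#' (e.g. gene symbols). Duplicate pairs and reversed duplicates are merged;
#' self-interactions are dropped with a warning, as the molecular networks this
#' package targets are simple graphs. Node order is first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab. Runs of the separator are
#'   collapsed, so whitespace-delimited files also parse.
#' @param comment_char lines starting with this character are skipped.
#' @return a \code{gfae_graph}.
#' @export
read_edge_list <- function(path, delimiter = "\t", comment_char = "#") {
  if (!file.exists(path)) stop("cannot read edge list: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment_char)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(new_graph(character(0), matrix(integer(0), ncol = 2L)))
  }
  split_re <- if (delimiter %in% c("\t", " ")) "[\t ]+" else
    paste0("[", delimiter, "]+")
  parts <- strsplit(trimws(lines[idx]), split_re)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("edge-list parse error: line %d has fewer than 2 columns",
                 idx[bad[1L]]))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-edge(s) from %s", sum(self), path))
    a <- a[!self]; b <- b[!self]
  }
  ids <- unique(c(rbind(a, b)))  # first-appearance order along lines
  ii <- match(a, ids); jj <- match(b, ids)
  n_raw <- length(ii)
  g <- new_graph(ids, cbind(ii, jj))
  dup <- n_raw - nrow(g$edges)
  if (dup > 0L) message(sprintf("deduplicated %d edge(s) in %s", dup, path))
  g
}

#' Write a graph as a two-column tab-separated edge list
#'
#' @param g a \code{gfae_graph}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(g, path) {
  df <- data.frame(from = g$node_ids[g$edges[, 1L]],
                   to   = g$node_ids[g$edges[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sparse adjacency matrix of a graph
#'
#' @param g a \code{gfae_graph}.
#' @param self_loops add the identity to the adjacency pattern.
#' @return a symmetric sparse \code{\link[Matrix]{Matrix}} of 0/1 entries.
#' @export
adjacency_matrix <- function(g, self_loops = FALSE) {
  n <- g$n_nodes
  e <- g$edges
  i <- c(e[, 1L], e[, 2L]); j <- c(e[, 2L], e[, 1L])
  if (self_loops) { i <- c(i, seq_len(n)); j <- c(j, seq_len(n)) }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' Symmetrically normalised adjacency with self-loops
#'
#' Computes the graph-convolution propagation operator
#' \eqn{\tilde A = D^{-1/2} (A + I) D^{-1/2}}, where \eqn{D} is the degree
#' matrix recomputed from \eqn{A + I}. Self-loops guarantee every node
#' (including isolated ones) has degree at least 1, and keep the operator's
#' spectrum in \eqn{[-1, 1]} so that repeated application is numerically
#' stable.
#'
#' @param g a \code{gfae_graph} with at least one node.
#' @return a symmetric sparse matrix with entries in \eqn{[0, 1]}.
#' @export
normalize_adjacency <- function(g) {
  if (g$n_nodes < 1L) stop("graph must have at least one node")
  a_hat <- adjacency_matrix(g, self_loops = TRUE)
  d <- Matrix::rowSums(a_hat)
  dinv <- 1 / sqrt(d)
  Matrix::Diagonal(x = dinv) %*% a_hat %*% Matrix::Diagonal(x = dinv)
}

#' Row-normalised closed-neighbourhood operator (mean pooling)
#'
#' \eqn{\hat D^{-1} (A + I)}: multiplying a feature matrix by this operator
#' replaces each node's row by the mean over the node and its neighbours.
#' This is the pooling used by the GraphSAGE and FeatGraphConv layers.
#'
#' @param g a \code{gfae_graph}.
#' @return a sparse row-stochastic matrix.
#' @export
mean_pool_operator <- function(g) {
  a_hat <- adjacency_matrix(g, self_loops = TRUE)
  d <- Matrix::rowSums(a_hat)
  Matrix::Diagonal(x = 1 / d) %*% a_hat
}

#' Node degrees
#' @param g a \code{gfae_graph}.
#' @param self_loops count a self-loop on every node (the convention of the
#'   normalised-adjacency operator).
#' @return integer vector of length \code{n_nodes}.
#' @export
degrees <- function(g, self_loops = FALSE) {
  d <- tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n_nodes)
  if (self_loops) d <- d + 1L
  d
}

#' Convert to / from igraph
#' @param g a \code{gfae_graph}.
#' @return an \code{\link[igraph]{igraph}} object with vertex name attributes.
#' @keywords internal
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  ig <- igraph::add_edges(ig, t(g$edges))
  igraph::set_vertex_attr(ig, "name", value = g$node_ids)
}

#' @keywords internal
from_igraph <- function(ig, node_ids = NULL) {
  if (is.null(node_ids)) {
    node_ids <- igraph::vertex_attr(ig, "name")
    if (is.null(node_ids)) node_ids <- as.character(seq_len(igraph::vcount(ig)))
  }
  new_graph(node_ids, igraph::as_edgelist(ig, names = FALSE))
}
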