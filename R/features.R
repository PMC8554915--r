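#' Read a gene-by-experiment expression table
#'
#' Expects a tab-separated file whose header row holds experiment identifiers
#' and whose first column holds gene identifiers; the body is numeric
#' (log-intensities, normalised counts, or any real-valued measurement).
#'
#' @param path path to the TSV file.
#' @return a numeric matrix (genes x experiments) with \code{rownames} = gene
#'   IDs and \code{colnames} = experiment IDs.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("cannot read expression table: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L && nrow(df) > 0L) stop("expression table needs a gene-ID column plus >=1 experiment column")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID in expression table: ",
         gene_ids[duplicated(gene_ids)][1L])
  }
  body <- df[, -1L, drop = FALSE]
  x <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  x <- matrix(x, nrow = nrow(df), ncol = ncol(body))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', experiment '%s'",
                 gene_ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  rownames(x) <- gene_ids
  colnames(x) <- colnames(body)
  x
}

#' Write a gene-by-experiment expression table
#'
#' Inverse of \code{\link{read_expression_table}}; used to emit imputed
#' matrices in the same dialect they were read in.
#'
#' @param x numeric matrix with gene rownames and experiment colnames.
#' @param path output file path.
#' @param id_column header of the gene-ID column.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a network and an expression matrix to their common genes
#'
#' Real network and expression resources rarely cover identical gene sets;
#' the common genes are extracted and both objects are restricted to them.
#' Edges with an endpoint outside the intersection are dropped. The shared
#' genes are ordered lexicographically so that repeated runs over the same
#' inputs produce identical node orderings.
#'
#' @param g a \code{gfae_graph}.
#' @param x expression matrix with gene rownames.
#' @return list with elements \code{graph} and \code{features}, row-aligned.
#' @export
align_graph_and_features <- function(g, x) {
  if (g$n_nodes == 0L || nrow(x) == 0L) stop("empty graph or feature matrix")
  common <- sort(intersect(g$node_ids, rownames(x)))
  if (length(common) == 0L) {
    stop("no genes shared between the network and the expression table")
  }
  idx_map <- match(g$node_ids, common)  # NA for dropped nodes
  e <- g$edges
  keep <- !is.na(idx_map[e[, 1L]]) & !is.na(idx_map[e[, 2L]])
  new_edges <- cbind(idx_map[e[keep, 1L]], idx_map[e[keep, 2L]])
  list(graph = new_graph(common, new_edges),
       features = x[common, , drop = FALSE])
}

#' Mean squared error over masked entries
#'
#' The loss used throughout the feature-prediction framework: the mean of
#' squared differences restricted to the entries selected by a binary mask.
#'
#' @param pred,target numeric matrices of equal shape.
#' @param mask binary matrix of the same shape; only entries with mask 1 (or
#'   \code{TRUE}) contribute.
#' @return scalar mean squared error.
#' @export
masked_mse <- function(pred, target, mask) {
  if (!all(dim(pred) == dim(target)) || !all(dim(pred) == dim(mask))) {
    stop("pred, target and mask must have identical dimensions")
  }
  m <- mask != 0
  k <- sum(m)
  if (k == 0L) stop("mask selects no entries")
  sum((pred[m] - target[m])^2) / k
}
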