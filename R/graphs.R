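#' K-nearest-neighbour graph construction
#'
#' Directed KNN edges are computed exactly (full distance matrix), with
#' distance ties broken in favour of the smaller spot index, then symmetrised
#' by OR: an undirected edge exists when either spot selects the other. The
#' result is a binary sparse adjacency with zero diagonal.
#'
#' @param x Numeric matrix whose rows are points (coordinates or embedding).
#' @param k Number of neighbours per point (1 <= k < nrow(x)).
#' @param kind "spatial" or "feature"; recorded on the result.
#' @return Object of class `neighbor_graph`: list with `adjacency` (N x N
#'   binary `dgCMatrix`), `kind`, `k_used`.
#' @keywords internal
knn_graph <- function(x, k, kind) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  # exact pairwise Euclidean distances; ties -> smaller index via stable sort
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  idx <- vapply(seq_len(n), function(i) {
    sort.int(d2[i, ], index.return = TRUE, method = "radix")$ix[seq_len(k)]
  }, integer(k))
  ii <- rep(seq_len(n), each = k)
  jj <- as.integer(idx)
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  a <- methods::as(a, "CsparseMatrix")
  a_sym <- a + Matrix::t(a)
  a_sym@x[] <- 1  # OR-symmetrisation: any positive entry becomes an edge
  structure(list(adjacency = Matrix::drop0(a_sym), kind = kind,
                 k_used = as.integer(k)),
            class = "neighbor_graph")
}

#' Spatial neighbour graph
#'
#' Links every spot to its `r` nearest spots by Euclidean distance on the
#' tissue coordinates (default r = 3), then symmetrises. Duplicate
#' coordinates are allowed; ties resolve to the smaller spot index.
#'
#' @param coords Spot-by-2 coordinate matrix.
#' @param r Number of nearest spots (default 3).
#' @return A `neighbor_graph` of kind "spatial".
#' @export
build_spatial_graph <- function(coords, r = 3L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must be spot-by-2")
  knn_graph(coords, r, "spatial")
}

#' Feature neighbour graph
#'
#' KNN graph (default k = 20) on the rows of the processed low-dimensional
#' embedding of one modality, capturing phenotypic proximity of spots that
#' may be spatially distant.
#'
#' @param h0 Spot-by-d embedding matrix (encoder input).
#' @param k Number of nearest neighbours (default 20).
#' @return A `neighbor_graph` of kind "feature".
#' @export
build_feature_graph <- function(h0, k = 20L) {
  knn_graph(as.matrix(h0), k, "feature")
}

#' Symmetrically normalised adjacency
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2}` (or without the identity when
#' `add_self_loops = FALSE`), where D holds the row sums. The output is
#' symmetric with spectral radius at most 1 and is the propagation operator
#' of every graph convolution in the model.
#'
#' @param graph A `neighbor_graph` or a square binary adjacency matrix.
#' @param add_self_loops Add the identity before normalising (default TRUE).
#' @return List of class `normalized_adjacency`: `matrix` (sparse symmetric),
#'   `self_loops`.
#' @export
symmetric_normalize <- function(graph, add_self_loops = TRUE) {
  a <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  a <- methods::as(a, "CsparseMatrix")
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (add_self_loops) a <- a + Matrix::Diagonal(nrow(a))
  deg <- Matrix::rowSums(a)
  if (any(deg == 0))
    stop("isolated node(s) with no self-loop: ",
         paste(utils::head(which(deg == 0), 5), collapse = ", "),
         "; enable add_self_loops or connect them")
  dinv <- Matrix::Diagonal(x = 1 / sqrt(deg))
  m <- dinv %*% a %*% dinv
  structure(list(matrix = methods::as(m, "CsparseMatrix"),
                 self_loops = isTRUE(add_self_loops)),
            class = "normalized_adjacency")
}

#' Export a graph as an edge list
#'
#' @param graph `neighbor_graph` or `normalized_adjacency`.
#' @param path Output TSV path (columns i, j, weight; upper triangle only).
#' @export
write_edge_list <- function(graph, path) {
  m <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph$matrix
  tm <- methods::as(m, "TsparseMatrix")
  keep <- tm@i <= tm@j
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                   weight = tm@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
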