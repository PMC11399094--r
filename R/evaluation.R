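#' Cluster the joint embedding into spatial domains
#'
#' "gmm" fits a full-covariance Gaussian mixture with exactly `n_clusters`
#' components (deterministic given the seed). Because a full covariance in
#' the raw latent dimension is ill-posed for small clusters (d(d+1)/2
#' parameters per component), the embedding is first reduced to its leading
#' `reduce_dim` principal components when it is wider than that; set
#' `reduce_dim = Inf` to disable. "leiden" builds a KNN graph
#' (k = 15) on the embedding and bisects the Leiden resolution in
#' [0.01, 3] until the community count hits the target (at most 40
#' iterations; the nearest count is returned with a warning otherwise).
#'
#' @param Z Spot-by-d embedding matrix.
#' @param n_clusters Target number of clusters.
#' @param method "gmm" (default) or "leiden".
#' @param seed Integer seed.
#' @param reduce_dim For "gmm": maximum embedding width before a PCA
#'   reduction is applied (default 20).
#' @return Integer label vector (1..n_clusters).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_latent <- function(Z, n_clusters, method = c("gmm", "leiden"),
                           seed = 0L, reduce_dim = 20L) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n_clusters > n) stop("n_clusters (", n_clusters,
                           ") exceeds number of spots (", n, ")")
  set.seed(seed)
  if (method == "gmm") {
    if (n_clusters == 1) return(rep(1L, n))
    if (is.finite(reduce_dim) && ncol(Z) > reduce_dim)
      Z <- unclass(pca_embed(Z, as.integer(reduce_dim)))[, , drop = FALSE]
    fit <- NULL
    for (mod in c("VVV", "EEE", "EII")) {
      fit <- suppressWarnings(
        mclust::Mclust(Z, G = n_clusters, modelNames = mod,
                       verbose = FALSE))
      if (!is.null(fit) && !is.null(fit$classification)) break
    }
    if (is.null(fit) || is.null(fit$classification)) {
      km <- stats::kmeans(Z, centers = n_clusters, nstart = 10,
                          iter.max = 100)
      return(as.integer(km$cluster))
    }
    return(as.integer(fit$classification))
  }
  # leiden on a KNN graph of the embedding
  k <- min(15L, n - 1L)
  adj <- knn_graph(Z, k, "feature")$adjacency
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  run <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      gr, objective_function = "modularity", resolution = res,
      n_iterations = 5))
  }
  lo <- 0.01; hi <- 3.0
  best <- NULL; best_gap <- Inf
  for (it in seq_len(40)) {
    mid <- (lo + hi) / 2
    mem <- run(mid)
    kc <- length(unique(mem))
    gap <- abs(kc - n_clusters)
    if (gap < best_gap) { best <- mem; best_gap <- gap }
    if (kc == n_clusters) return(as.integer(mem))
    if (kc < n_clusters) lo <- mid else hi <- mid
  }
  warning("leiden bisection did not reach ", n_clusters, " clusters; ",
          "returning ", length(unique(best)))
  as.integer(best)
}

#' Per-cluster Moran's I of cluster membership
#'
#' Spatial autocorrelation of each cluster's one-hot indicator over a binary
#' symmetrised spatial KNN weight graph:
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Spatially coherent domains score near 1, salt-and-pepper labels near
#' `-1/(N-1)`.
#'
#' @param labels Cluster label vector.
#' @param coords Spot-by-2 coordinates (ignored when `weights` is given).
#' @param k_weights Neighbours of the weight graph (default 6, approximating
#'   hexagonal array adjacency).
#' @param weights Optional N x N spatial weight matrix overriding the KNN
#'   construction (e.g. rook adjacency on a grid).
#' @return Named numeric vector, one Moran's I per cluster; NaN (with a
#'   warning) for a cluster containing every spot.
#' @export
morans_i <- function(labels, coords = NULL, k_weights = 6L, weights = NULL) {
  n <- length(labels)
  if (is.null(weights)) {
    if (is.null(coords)) stop("need coords or weights")
    weights <- knn_graph(as.matrix(coords), k_weights, "spatial")$adjacency
  }
  w <- methods::as(methods::as(weights, "CsparseMatrix"), "TsparseMatrix")
  w_sum <- sum(w@x)
  levs <- sort(unique(labels))
  out <- vapply(levs, function(lv) {
    x <- as.numeric(labels == lv)
    xc <- x - mean(x)
    denom <- sum(xc^2)
    if (denom == 0) {
      warning("cluster ", lv, " contains all spots; Moran's I undefined")
      return(NaN)
    }
    num <- sum(w@x * xc[w@i + 1L] * xc[w@j + 1L])
    (n / w_sum) * num / denom
  }, numeric(1))
  names(out) <- as.character(levs)
  out
}

knn_sets <- function(x, k) {
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  lapply(seq_len(nrow(d2)), function(i)
    sort.int(d2[i, ], index.return = TRUE, method = "radix")$ix[seq_len(k)])
}

#' Neighbour-set Jaccard preservation
#'
#' For every spot, the Jaccard index between its k-nearest-neighbour set in
#' the joint embedding and in each modality's own embedding, averaged over
#' spots. High values mean the joint space preserves that modality's local
#' geometry; `total` sums the per-modality means.
#'
#' @param Z Joint spot-by-d embedding.
#' @param modality_embeddings List (ideally named) of per-modality spot-by-d
#'   embeddings.
#' @param k Neighbourhood size (default 20).
#' @return List `per_modality` (named mean Jaccard values) and `total`.
#' @export
jaccard_preservation <- function(Z, modality_embeddings, k = 20L) {
  n <- nrow(Z)
  if (k >= n) stop("k must be smaller than the number of spots")
  sz <- knn_sets(as.matrix(Z), k)
  per <- vapply(modality_embeddings, function(h) {
    sh <- knn_sets(as.matrix(h), k)
    mean(vapply(seq_len(n), function(i) {
      inter <- length(intersect(sz[[i]], sh[[i]]))
      inter / (2 * k - inter)
    }, numeric(1)))
  }, numeric(1))
  if (is.null(names(per)))
    names(per) <- paste0("modality", seq_along(per))
  list(per_modality = per, total = sum(per))
}

entropy_nats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expected mutual information under the permutation model (hypergeometric),
# used by the adjusted mutual information.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      ai <- a[i]; bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum((nij / n) * log(n * nij / (ai * bj)) * exp(log_p))
    }
  }
  emi
}

#' Supervised clustering agreement scores
#'
#' The six standard external scores from the truth-by-prediction contingency
#' table: homogeneity, mutual information (nats), V-measure, adjusted mutual
#' information (max normalisation), normalised mutual information
#' (arithmetic-mean normalisation) and the adjusted Rand index.
#'
#' @param pred_labels,truth_labels Equal-length label vectors; truth must
#'   have at least 2 classes.
#' @return Named numeric vector `homogeneity`, `mutual_information`,
#'   `v_measure`, `AMI`, `NMI`, `ARI`.
#' @export
supervised_scores <- function(pred_labels, truth_labels) {
  if (length(pred_labels) != length(truth_labels))
    stop("label vectors have different lengths")
  n <- length(pred_labels)
  tab <- table(truth = truth_labels, pred = pred_labels)
  a <- rowSums(tab)  # truth class sizes
  b <- colSums(tab)  # predicted cluster sizes
  if (length(a) < 2) stop("truth labels must contain at least 2 classes")
  h_c <- entropy_nats(a)
  h_k <- entropy_nats(b)
  nz <- tab > 0
  mi <- sum((tab[nz] / n) *
              log((tab[nz] / n) /
                    (outer(a, b)[nz] / n^2)))
  mi <- max(mi, 0)
  homogeneity <- if (h_c == 0) 1 else mi / h_c
  completeness <- if (h_k == 0) 1 else mi / h_k
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  nmi <- if (h_c + h_k == 0) 1 else mi / ((h_c + h_k) / 2)
  emi <- expected_mi(a, b, n)
  denom_ami <- max(h_c, h_k) - emi
  ami <- if (abs(denom_ami) < 1e-15) 1 else (mi - emi) / denom_ami
  # adjusted Rand index by pair counting
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(as.numeric(tab)))
  sum_a <- sum(comb2(as.numeric(a)))
  sum_b <- sum(comb2(as.numeric(b)))
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else
    (sum_ij - exp_idx) / (max_idx - exp_idx)
  c(homogeneity = homogeneity, mutual_information = mi, v_measure = v,
    AMI = ami, NMI = nmi, ARI = ari)
}

#' Best-match F1 score for one ground-truth class
#'
#' Maps each predicted cluster to its best F1 against the indicator of one
#' truth class and returns the maximum — how well any single predicted
#' cluster recovers that class.
#'
#' @param pred_labels Predicted cluster labels.
#' @param truth_labels Ground-truth labels.
#' @param class The truth class of interest.
#' @return F1 in [0, 1].
#' @export
best_match_f1 <- function(pred_labels, truth_labels, class) {
  truth_ind <- truth_labels == class
  if (!any(truth_ind)) stop("class ", class, " absent from truth labels")
  max(vapply(unique(pred_labels), function(cl) {
    pred_ind <- pred_labels == cl
    tp <- sum(pred_ind & truth_ind)
    if (tp == 0) return(0)
    prec <- tp / sum(pred_ind)
    rec <- tp / sum(truth_ind)
    2 * prec * rec / (prec + rec)
  }, numeric(1)))
}
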