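#' Filter spots and features on minimum detection
#'
#' Two passes, applied once each: first features detected (nonzero) in fewer
#' than `min_spots_per_feature` spots are dropped, then spots with fewer than
#' `min_features_per_spot` detected features among the kept ones are dropped.
#'
#' @param counts Spot-by-feature count matrix (dense or sparse).
#' @param min_features_per_spot,min_spots_per_feature Non-negative integer
#'   thresholds (0 disables a pass).
#' @return List `counts` (reduced matrix), `kept_spots`, `kept_features`
#'   (integer index vectors into the input).
#' @export
filter_counts <- function(counts, min_features_per_spot = 0L,
                          min_spots_per_feature = 0L) {
  stopifnot(min_features_per_spot >= 0, min_spots_per_feature >= 0)
  nz <- counts > 0
  kept_features <- which(Matrix::colSums(nz) >= min_spots_per_feature)
  nz <- nz[, kept_features, drop = FALSE]
  kept_spots <- which(Matrix::rowSums(nz) >= min_features_per_spot)
  if (length(kept_spots) == 0)
    stop("filtering removed every spot; relax min_features_per_spot (",
         min_features_per_spot, ")")
  if (length(kept_features) == 0)
    stop("filtering removed every feature; relax min_spots_per_feature (",
         min_spots_per_feature, ")")
  list(counts = counts[kept_spots, kept_features, drop = FALSE],
       kept_spots = kept_spots, kept_features = kept_features)
}

#' Library-size normalisation and log transform
#'
#' Scales each spot so its total count equals the target (the median
#' pre-scaling spot total by default), then applies log1p.
#'
#' @param counts Spot-by-feature non-negative matrix.
#' @param target "median" or a positive number.
#' @return Dense spot-by-feature matrix of log-normalised values.
#' @export
lognorm_rna <- function(counts, target = "median") {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("spot(s) with zero total count: ",
         paste(utils::head(which(totals == 0), 5), collapse = ", "),
         "; filter them out first")
  tgt <- if (identical(target, "median")) stats::median(totals)
         else as.numeric(target)
  stopifnot(tgt > 0)
  x <- as.matrix(counts) * (tgt / totals)
  log1p(x)
}

#' Select highly variable features by binned normalised dispersion
#'
#' The standard single-cell dispersion criterion: on the de-logged
#' (normalised count) scale, each feature's dispersion `var/mean` is
#' log-transformed and z-scored within 20 equal-width bins of `log1p(mean)`;
#' the top `n_hvg` features by normalised dispersion are kept. Bins with
#' fewer than three features (or zero spread) are normalised against the
#' global dispersion distribution so isolated features remain rankable.
#' Ties break by feature index, so the selection is deterministic.
#'
#' @param lognorm Spot-by-feature matrix of log-normalised values.
#' @param n_hvg Number of features to keep; if >= feature count, all are kept
#'   with a warning.
#' @param n_bins Number of mean bins (default 20).
#' @return Sorted integer vector of selected feature indices.
#' @export
select_hvg <- function(lognorm, n_hvg = 3000L, n_bins = 20L) {
  d <- ncol(lognorm)
  if (n_hvg >= d) {
    if (n_hvg > d) warning("n_hvg (", n_hvg, ") >= feature count (", d,
                           "); keeping all features")
    return(seq_len(d))
  }
  x <- expm1(lognorm)                 # back to the normalised-count scale
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ld <- ifelse(disp > 0, log(disp), NA_real_)
  bins <- cut(log1p(mu), breaks = min(n_bins, d), labels = FALSE,
              include.lowest = TRUE)
  z <- ld
  g_m <- mean(ld, na.rm = TRUE)
  g_s <- stats::sd(ld, na.rm = TRUE)
  for (b in unique(bins)) {
    in_b <- which(bins == b)
    m <- mean(ld[in_b], na.rm = TRUE)
    s <- stats::sd(ld[in_b], na.rm = TRUE)
    if (length(in_b) < 3 || is.na(s) || s == 0) {
      # sparse or constant bin: normalise against the global spread so such
      # features are still rankable
      z[in_b] <- if (is.na(g_s) || g_s == 0) 0 else (ld[in_b] - g_m) / g_s
    } else {
      z[in_b] <- (ld[in_b] - m) / s
    }
  }
  z[is.na(z)] <- -Inf                 # zero-variance features rank last
  # rank by decreasing normalised dispersion, ties by smaller feature index
  ord <- order(-z, seq_len(d))
  sort(ord[seq_len(n_hvg)])
}

#' Centred log-ratio normalisation
#'
#' Per spot: `clr(x)_j = log(x_j + 1) - mean_j log(x_j + 1)`. The +1
#' pseudocount handles the pervasive zeros of antibody-derived tag counts;
#' each output row sums to zero.
#'
#' @param counts Spot-by-feature non-negative matrix.
#' @return Dense spot-by-feature matrix with zero row means.
#' @export
clr_normalize <- function(counts) {
  lg <- log1p(as.matrix(counts))
  lg - rowMeans(lg)
}

#' PCA embedding with a deterministic sign convention
#'
#' Column-centres the input and projects onto the leading principal
#' components. Each component's sign is fixed so that its largest-magnitude
#' loading is positive, removing run-to-run sign flips.
#'
#' @param x Spot-by-feature numeric matrix.
#' @param n_components Number of components (<= min(N - 1, features)).
#' @return Spot-by-`n_components` score matrix with attributes `sdev`
#'   (component standard deviations) and `rotation`.
#' @export
pca_embed <- function(x, n_components) {
  x <- as.matrix(x)
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > k_max)
    stop("n_components (", n_components, ") exceeds min(N-1, d) = ", k_max)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- p$rotation
  sc <- p$x
  for (j in seq_len(ncol(rot))) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  structure(sc, sdev = p$sdev[seq_len(n_components)], rotation = rot)
}

#' TF-IDF latent semantic indexing for chromatin counts
#'
#' Term frequency per spot, inverse document frequency `log(1 + N/df)`, then
#' `log1p(tf * idf * 1e4)` and a truncated SVD; all `n_components` components
#' are returned with the same sign convention as [pca_embed()].
#'
#' @param counts Spot-by-peak non-negative matrix.
#' @param n_components Embedding dimension.
#' @return Spot-by-`n_components` matrix (U * d) with attribute `d` (singular
#'   values).
#' @export
lsi_embed <- function(counts, n_components) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("spot(s) with zero total count: ",
         paste(utils::head(which(totals == 0), 5), collapse = ", "))
  n <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  idf <- log(1 + n / pmax(df, .Machine$double.eps))
  tf <- as.matrix(counts) / totals
  y <- log1p(sweep(tf, 2, idf, `*`) * 1e4)
  k_max <- min(dim(y))
  if (n_components > k_max)
    stop("n_components (", n_components, ") exceeds min(N, d) = ", k_max)
  s <- svd(y, nu = n_components, nv = n_components)
  u <- s$u
  v <- s$v
  for (j in seq_len(n_components)) {
    flip <- sign(v[which.max(abs(v[, j])), j])
    if (flip < 0) { u[, j] <- -u[, j] }
  }
  emb <- u %*% diag(s$d[seq_len(n_components)], n_components)
  structure(emb, d = s$d[seq_len(n_components)])
}

#' Prepare encoder inputs for every modality
#'
#' Applies the omics-specific recipe to each modality and fills its
#' `processed` slot: RNA counts are library-size log-normalised, reduced to
#' highly variable genes and embedded by PCA; protein (ADT) counts are
#' CLR-normalised then embedded by PCA; chromatin peak counts go through
#' TF-IDF LSI. All modalities are embedded to a common dimension
#' `d_in = min_m min(50, post-filter feature count of m)` (or the configured
#' `d_in`), so that encoders share an input size. Idempotent: a second call
#' reproduces identical embeddings.
#'
#' @param dataset A `spatial_dataset`.
#' @param config A [duet_config()]; `d_in = "auto"` resolves here.
#' @param min_features_per_spot,min_spots_per_feature Detection filters
#'   applied to each modality before normalisation (defaults 0: the caller
#'   filters explicitly when needed, so spot sets stay aligned across
#'   modalities).
#' @return The dataset with `processed` filled in and attribute `d_in` set on
#'   each modality; `dataset$d_in` records the common dimension.
#' @export
prepare_inputs <- function(dataset, config = duet_config(),
                           min_features_per_spot = 0L,
                           min_spots_per_feature = 0L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  n <- dataset$n_spots
  mods <- dataset$modalities
  feat_counts <- integer(length(mods))
  filtered <- vector("list", length(mods))
  for (i in seq_along(mods)) {
    f <- filter_counts(mods[[i]]$counts, 0L, min_spots_per_feature)
    if (length(f$kept_spots) != n)
      stop("feature-only filtering must keep all spots")
    filtered[[i]] <- f$counts
    feat_counts[i] <- ncol(f$counts)
  }
  d_in <- if (identical(config$d_in, "auto")) {
    min(pmin(50L, feat_counts), n - 1L)
  } else as.integer(config$d_in)
  if (d_in < 2) stop("resolved input dimension d_in = ", d_in, " (< 2); ",
                     "modalities have too few features")
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    cnt <- filtered[[i]]
    h0 <- switch(m$omics_type,
      rna = {
        ln <- lognorm_rna(cnt, config$lognorm_target)
        hv <- select_hvg(ln, config$n_hvg)
        pca_embed(ln[, hv, drop = FALSE], d_in)
      },
      protein = pca_embed(clr_normalize(cnt), d_in),
      chromatin = lsi_embed(cnt, d_in))
    m$processed <- as.matrix(h0)[, seq_len(d_in), drop = FALSE]
    rownames(m$processed) <- rownames(dataset$coordinates)
    mods[[i]] <- m
  }
  dataset$modalities <- mods
  dataset$d_in <- d_in
  dataset
}
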