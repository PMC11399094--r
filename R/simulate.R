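# Synthetic spatial multi-omics benchmark: four spatial factor regions on a
# grid plus background, with each factor driven by a marker block in the
# modalities that are "informative" for it. Modality 1 draws zero-inflated
# negative binomial counts (transcriptome-like), modality 2 plain negative
# binomial (proteome-like).

#' Default spatial factor layout
#'
#' Four disjoint regions in unit-square fractions of the grid: two rectangles
#' in the upper half (factors 1 and 3), a central disc (factor 2) and a lower
#' rectangle (factor 4); everything else is background (label 0).
#'
#' @return List of region descriptors (`shape`, extents in [0, 1]).
#' @export
default_factor_layout <- function() {
  list(
    list(shape = "rect", x0 = 0.05, x1 = 0.35, y0 = 0.55, y1 = 0.95),
    list(shape = "circle", cx = 0.50, cy = 0.50, r = 0.15),
    list(shape = "rect", x0 = 0.65, x1 = 0.95, y0 = 0.60, y1 = 0.90),
    list(shape = "rect", x0 = 0.10, x1 = 0.45, y0 = 0.05, y1 = 0.30))
}

#' Build the ground-truth factor map
#'
#' Places the layout's regions on a `rows x cols` lattice. Labels are 0 for
#' background and 1..n_factors for the regions; overlapping regions raise an
#' error.
#'
#' @param grid Integer vector (rows, cols).
#' @param layout List of region descriptors (see [default_factor_layout()]).
#' @return List `labels` (integer vector, spot order = row-major grid) and
#'   `coordinates` (spot-by-2 matrix of lattice positions).
#' @export
make_spatial_factors <- function(grid = c(50L, 50L),
                                 layout = default_factor_layout()) {
  rows <- grid[1]; cols <- grid[2]
  pos <- expand.grid(x = seq_len(cols), y = seq_len(rows))
  fx <- (pos$x - 0.5) / cols
  fy <- (pos$y - 0.5) / rows
  labels <- integer(nrow(pos))
  for (f in seq_along(layout)) {
    rg <- layout[[f]]
    inside <- if (rg$shape == "rect") {
      fx >= rg$x0 & fx <= rg$x1 & fy >= rg$y0 & fy <= rg$y1
    } else if (rg$shape == "circle") {
      (fx - rg$cx)^2 + (fy - rg$cy)^2 <= rg$r^2
    } else stop("unknown shape '", rg$shape, "'")
    if (any(labels[inside] != 0))
      stop("factor ", f, " overlaps factor ",
           labels[inside][labels[inside] != 0][1])
    labels[inside] <- f
  }
  coords <- as.matrix(pos)
  rownames(coords) <- sprintf("spot%04d", seq_len(nrow(coords)))
  list(labels = labels, coordinates = coords)
}

#' Sample negative binomial counts
#'
#' Independent draws with mean `mu` and dispersion `theta`
#' (variance `mu + mu^2/theta`).
#'
#' @param mean_matrix Spot-by-feature matrix of non-negative means.
#' @param theta Dispersion (> 0); larger values approach Poisson.
#' @param seed Integer seed.
#' @return Integer count matrix of the same shape.
#' @export
sample_nb_counts <- function(mean_matrix, theta, seed = 0L) {
  stopifnot(theta > 0, all(mean_matrix >= 0))
  set.seed(seed)
  m <- matrix(stats::rnbinom(length(mean_matrix), mu = as.numeric(mean_matrix),
                             size = theta),
              nrow(mean_matrix), ncol(mean_matrix),
              dimnames = dimnames(mean_matrix))
  m
}

#' Sample zero-inflated negative binomial counts
#'
#' A negative binomial draw (same seed pathway as [sample_nb_counts()], so
#' `pi = 0` reproduces it exactly) zeroed independently per entry with
#' probability `pi`.
#'
#' @param mean_matrix Spot-by-feature matrix of non-negative means.
#' @param theta Dispersion (> 0).
#' @param pi Dropout (zero-inflation) probability in [0, 1].
#' @param seed Integer seed.
#' @return Integer count matrix.
#' @export
sample_zinb_counts <- function(mean_matrix, theta, pi = 0, seed = 0L) {
  stopifnot(pi >= 0, pi <= 1)
  m <- sample_nb_counts(mean_matrix, theta, seed)
  if (pi > 0) {
    drop <- matrix(stats::runif(length(m)) < pi, nrow(m), ncol(m))
    m[drop] <- 0L
  }
  m
}

# Spot-by-feature mean matrix: baseline everywhere, marker blocks multiplied
# by fold_change inside the spots of factors this modality is informative
# for. Marker blocks are disjoint: factor f owns features
# ((f-1)*width, f*width].
factor_mean_matrix <- function(labels, n_features, informative_factors,
                               baseline_mean, fold_change,
                               marker_fraction = 0.1) {
  n <- length(labels)
  width <- max(1L, floor(marker_fraction * n_features))
  mu <- matrix(baseline_mean, n, n_features)
  for (f in informative_factors) {
    feats <- ((f - 1L) * width + 1L):(f * width)
    if (max(feats) > n_features)
      stop("marker blocks exceed n_features; increase n_features")
    mu[labels == f, feats] <- baseline_mean * fold_change
  }
  mu
}

#' Generate a synthetic spatial multi-omics benchmark
#'
#' Emulates the two-modality simulation design: four spatial factors on a
#' grid, with factors 1, 3 and 4 carried only by modality 1 (zero-inflated
#' negative binomial, transcriptome-like) and factor 2 only by modality 2
#' (negative binomial, proteome-like), so neither modality alone can resolve
#' all domains. Presets `alt1`..`alt4` perturb dropout, dispersion, fold
#' change and baseline to give five simulated samples; `three_modality`
#' splits factor information across three modalities (the third chromatin-
#' like, preprocessed by LSI).
#'
#' @param preset One of "default", "alt1".."alt4", "three_modality".
#' @param seed Integer seed; identical seeds give bitwise-identical datasets.
#' @param grid Lattice size (rows, cols); default 50 x 50 = 2500 spots.
#' @return List `dataset` (a `spatial_dataset` with truth labels) and
#'   `truth` (list `labels`, `coordinates`).
#' @export
generate_benchmark <- function(preset = c("default", "alt1", "alt2", "alt3",
                                          "alt4", "three_modality"),
                               seed = 0L, grid = c(50L, 50L)) {
  preset <- match.arg(preset)
  gt <- make_spatial_factors(grid)
  # per-modality generative settings; defaults are the study conditions
  base <- list(
    m1 = list(n_features = 200L, baseline_mean = 2, fold_change = 5,
              theta = 2, pi = 0.4, informative = c(1L, 3L, 4L),
              dist = "zinb", omics = "rna", name = "rna"),
    m2 = list(n_features = 50L, baseline_mean = 5, fold_change = 5,
              theta = 2, pi = 0, informative = 2L,
              dist = "nb", omics = "protein", name = "adt"))
  mods_spec <- switch(preset,
    default = base,
    alt1 = { b <- base; b$m1$pi <- 0.6; b },
    alt2 = { b <- base; b$m1$theta <- 0.5; b$m2$theta <- 0.5; b },
    alt3 = { b <- base; b$m1$fold_change <- 3; b$m2$fold_change <- 3; b },
    alt4 = { b <- base; b$m1$baseline_mean <- 4; b$m2$baseline_mean <- 10
             b$m1$fold_change <- 4; b$m2$fold_change <- 4; b },
    three_modality = {
      b <- base
      b$m1$informative <- c(1L, 3L)
      b$m3 <- list(n_features = 100L, baseline_mean = 3, fold_change = 5,
                   theta = 2, pi = 0, informative = 4L,
                   dist = "nb", omics = "chromatin", name = "atac")
      b
    })
  modalities <- vector("list", length(mods_spec))
  for (i in seq_along(mods_spec)) {
    sp <- mods_spec[[i]]
    mu <- factor_mean_matrix(gt$labels, sp$n_features, sp$informative,
                             sp$baseline_mean, sp$fold_change)
    cnt <- if (sp$dist == "zinb") {
      sample_zinb_counts(mu, sp$theta, sp$pi, seed = seed + i)
    } else {
      sample_nb_counts(mu, sp$theta, seed = seed + i)
    }
    rownames(cnt) <- rownames(gt$coordinates)
    colnames(cnt) <- sprintf("%s_feat%03d", sp$name, seq_len(sp$n_features))
    modalities[[i]] <- modality_data(sp$name, sp$omics, cnt)
  }
  dataset <- assemble_dataset(modalities, gt$coordinates, truth = gt$labels)
  list(dataset = dataset, truth = gt)
}

#' Write a simulated benchmark to disk
#'
#' One MatrixMarket triplet per modality (`<name>/matrix.mtx` with
#' `features.tsv` and `barcodes.tsv`, feature-by-spot on disk per 10x
#' convention) plus `coords.tsv` and `truth.tsv`, directly consumable by
#' [load_counts()] and [load_coordinates()].
#'
#' @param sim Result of [generate_benchmark()].
#' @param out_dir Output directory.
#' @export
write_benchmark <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  for (m in ds$modalities) {
    d <- file.path(out_dir, m$name)
    dir.create(d, showWarnings = FALSE)
    Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(m$counts,
                                                         sparse = TRUE)),
                                "generalMatrix"),
                    file.path(d, "matrix.mtx"))
    utils::write.table(data.frame(id = m$feature_names,
                                  name = m$feature_names),
                       file.path(d, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(rownames(ds$coordinates),
                       file.path(d, "barcodes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(spot = rownames(ds$coordinates),
                                ds$coordinates),
                     file.path(out_dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(spot = rownames(ds$coordinates),
                                label = sim$truth$labels),
                     file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
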