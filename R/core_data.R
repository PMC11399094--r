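#' Create a single-modality container
#'
#' Bundles one omics layer of a spatial multi-omics experiment: the raw
#' spot-by-feature count matrix, an optional processed low-dimensional
#' embedding (the encoder input), and feature names.
#'
#' @param name Character label for the modality (e.g. "rna", "adt").
#' @param omics_type One of "rna", "protein", "chromatin"; selects the
#'   preprocessing recipe in [prepare_inputs()].
#' @param counts Spot-by-feature matrix of non-negative counts (dense matrix
#'   or [Matrix::sparseMatrix()]). Spots are rows.
#' @param feature_names Optional character vector, length `ncol(counts)`.
#'   Defaults to existing column names or `feat1..featD`.
#' @param processed Optional spot-by-d numeric matrix, the low-dimensional
#'   encoder input. Usually filled in by [prepare_inputs()].
#' @return An object of class `modality_data`.
#' @export
modality_data <- function(name, omics_type = c("rna", "protein", "chromatin"),
                          counts, feature_names = NULL, processed = NULL) {
  omics_type <- match.arg(omics_type)
  if (!(is.matrix(counts) || inherits(counts, "Matrix")))
    stop("'counts' must be a matrix or Matrix")
  if (min_val(counts) < 0)
    stop("modality '", name, "': counts contain negative entries")
  if (is.null(feature_names)) {
    feature_names <- colnames(counts)
    if (is.null(feature_names))
      feature_names <- paste0("feat", seq_len(ncol(counts)))
  }
  if (length(feature_names) != ncol(counts))
    stop("feature_names length (", length(feature_names),
         ") != number of features (", ncol(counts), ")")
  colnames(counts) <- feature_names
  if (!is.null(processed)) {
    processed <- as.matrix(processed)
    if (nrow(processed) != nrow(counts))
      stop("processed matrix row count differs from counts")
  }
  structure(
    list(name = name, omics_type = omics_type, counts = counts,
         processed = processed, feature_names = feature_names),
    class = "modality_data")
}

# minimum over dense or sparse matrices without densifying
min_val <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    v <- methods::slot(methods::as(x, "CsparseMatrix"), "x")
    if (length(v) < nrow(x) * ncol(x)) min(0, v) else min(v)
  } else min(x)
}

#' Assemble a spatial multi-omics dataset
#'
#' Validates and bundles two or more modalities measured on the same set of
#' spots together with spot coordinates and optional ground-truth labels.
#' Spots are aligned across inputs by shared spot ID (row names) when all
#' inputs carry them, and by row order otherwise; same-section assays share
#' barcodes, so ID alignment is the default whenever possible.
#'
#' @param modalities List of [modality_data()] objects (length >= 2, or >= 1
#'   with `allow_single = TRUE` for unimodal baselines).
#' @param coords Spot-by-2 numeric matrix of planar coordinates (arbitrary but
#'   consistent units; only relative distances matter).
#' @param truth Optional integer/factor vector of ground-truth domain labels.
#' @param allow_single Allow a single modality (default FALSE).
#' @return An object of class `spatial_dataset` with elements `n_spots`,
#'   `coordinates`, `modalities`, `spatial_graph` (NULL until built),
#'   `truth_labels`.
#' @export
assemble_dataset <- function(modalities, coords, truth = NULL,
                             allow_single = FALSE) {
  if (inherits(modalities, "modality_data")) modalities <- list(modalities)
  m_min <- if (allow_single) 1L else 2L
  if (length(modalities) < m_min)
    stop("need at least ", m_min, " modalities, got ", length(modalities))
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have exactly 2 columns")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  n <- nrow(coords)

  ids <- rownames(coords)
  have_ids <- !is.null(ids) &&
    all(vapply(modalities, function(m) !is.null(rownames(m$counts)), TRUE))
  for (m in modalities) {
    if (nrow(m$counts) != n)
      stop("modality '", m$name, "' has ", nrow(m$counts),
           " spots but coordinates have ", n)
  }
  if (have_ids) {
    for (i in seq_along(modalities)) {
      m <- modalities[[i]]
      missing <- setdiff(ids, rownames(m$counts))
      if (length(missing) > 0)
        stop("modality '", m$name, "' is missing spot IDs: ",
             paste(utils::head(missing, 5), collapse = ", "))
      ord <- match(ids, rownames(m$counts))
      m$counts <- m$counts[ord, , drop = FALSE]
      if (!is.null(m$processed))
        m$processed <- m$processed[ord, , drop = FALSE]
      modalities[[i]] <- m
    }
  }
  if (!is.null(truth)) {
    if (length(truth) != n) stop("truth labels length != number of spots")
    truth <- if (is.numeric(truth)) as.integer(truth)
             else as.integer(as.factor(truth))
  }
  nm <- vapply(modalities, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("modality names must be unique")
  names(modalities) <- nm
  structure(
    list(n_spots = n, coordinates = coords, modalities = modalities,
         spatial_graph = NULL, truth_labels = truth),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", x$n_spots, "spots,",
      length(x$modalities), "modalities\n")
  for (m in x$modalities) {
    d_proc <- if (is.null(m$processed)) "unprocessed"
              else paste0("d_in=", ncol(m$processed))
    cat(sprintf("  %s (%s): %d features, %s\n",
                m$name, m$omics_type, ncol(m$counts), d_proc))
  }
  if (!is.null(x$truth_labels))
    cat("  ground truth:", length(unique(x$truth_labels)), "classes\n")
  invisible(x)
}

#' Read a spot-by-feature count matrix
#'
#' Supports 10x-style MatrixMarket triplets (`matrix.mtx` with sibling
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`) and delimited text with a
#' header row. MTX input is feature-by-spot on disk by 10x convention and is
#' transposed to spot-by-feature unless `mtx_spots_are_rows = TRUE`; sparse
#' storage is preserved. HDF5-based containers are not supported; export to
#' MTX or CSV first.
#'
#' @param path Path to the `.mtx`/`.csv`/`.tsv` file.
#' @param fmt Format; inferred from the extension by default.
#' @param mtx_spots_are_rows Set TRUE when an MTX file already stores spots as
#'   rows.
#' @return List with `counts` (spot-by-feature, sparse for MTX) and
#'   `feature_names`.
#' @export
load_counts <- function(path, fmt = c("auto", "mtx", "csv", "tsv", "h5ad"),
                        mtx_spots_are_rows = FALSE) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                  h5ad = "h5ad", h5 = "h5ad",
                  stop("cannot infer format from extension of ", path))
  }
  if (fmt == "h5ad")
    stop("h5ad input is not supported; export counts to MTX or CSV ",
         "(e.g. with scanpy/anndata) and load those instead")
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "mtx") {
    mat <- tryCatch(Matrix::readMM(path),
                    error = function(e) stop("malformed MatrixMarket file ",
                                             path, ": ", conditionMessage(e)))
    mat <- methods::as(mat, "CsparseMatrix")
    dir <- dirname(path)
    feat_path <- Filter(file.exists, file.path(dir, c(
      "features.tsv", "genes.tsv", "features.tsv.gz", "genes.tsv.gz")))
    bc_path <- Filter(file.exists, file.path(dir, c(
      "barcodes.tsv", "barcodes.tsv.gz")))
    if (!mtx_spots_are_rows) mat <- Matrix::t(mat)
    if (length(feat_path) > 0) {
      ft <- utils::read.delim(feat_path[1], header = FALSE,
                              stringsAsFactors = FALSE)
      # 10x features.tsv: id, name, type; use the first column as identifier
      if (nrow(ft) != ncol(mat))
        stop("features file has ", nrow(ft), " rows but matrix has ",
             ncol(mat), " features")
      colnames(mat) <- make.unique(as.character(ft[[1]]))
    }
    if (length(bc_path) > 0) {
      bc <- utils::read.delim(bc_path[1], header = FALSE,
                              stringsAsFactors = FALSE)
      if (nrow(bc) != nrow(mat))
        stop("barcodes file has ", nrow(bc), " rows but matrix has ",
             nrow(mat), " spots")
      rownames(mat) <- as.character(bc[[1]])
    }
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        row.names = 1, stringsAsFactors = FALSE),
      error = function(e) stop("malformed ", fmt, " file ", path, ": ",
                               conditionMessage(e)))
    mat <- as.matrix(df)
    storage.mode(mat) <- "double"
    if (any(!is.finite(mat)))
      stop("non-numeric or non-finite entries in ", path)
  }
  if (min_val(mat) < 0)
    stop("count matrix in ", path, " has negative entries")
  list(counts = mat, feature_names = colnames(mat))
}

#' Read spot coordinates
#'
#' Expects a delimited file with two numeric columns (x, y) and optionally a
#' leading spot-ID column. When `spot_ids` is supplied (e.g. the row names of
#' a count matrix), rows are reordered to match; spot IDs present in the
#' counts but absent here raise an error.
#'
#' @param path Path to a CSV/TSV file.
#' @param spot_ids Optional character vector of spot IDs defining the target
#'   order.
#' @return Spot-by-2 numeric matrix (columns x, y), row names = spot IDs when
#'   available.
#' @export
load_coordinates <- function(path, spot_ids = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  id_col <- which(!vapply(df, is.numeric, TRUE))
  if (length(id_col) > 1) stop("more than one non-numeric column in ", path)
  ids <- NULL
  if (length(id_col) == 1) {
    ids <- as.character(df[[id_col]])
    df <- df[-id_col]
  }
  if (ncol(df) < 2) stop("coordinate file needs two numeric columns")
  coords <- as.matrix(df[, 1:2])
  colnames(coords) <- c("x", "y")
  if (any(!is.finite(coords)))
    stop("non-finite coordinates at rows: ",
         paste(utils::head(which(rowSums(!is.finite(coords)) > 0), 5),
               collapse = ", "))
  if (!is.null(ids)) rownames(coords) <- ids
  if (!is.null(spot_ids)) {
    if (is.null(ids))
      stop("spot_ids given but the coordinate file has no ID column")
    missing <- setdiff(spot_ids, ids)
    if (length(missing) > 0)
      stop("coordinates missing for spots: ",
           paste(utils::head(missing, 5), collapse = ", "))
    coords <- coords[match(spot_ids, ids), , drop = FALSE]
  }
  coords
}

#' Write a fitted integration result to disk
#'
#' Writes the joint embedding, attention weights, clusters (if present), the
#' per-epoch loss trace and a JSON snapshot of the configuration as plain-text
#' files that [load_results()] reads back (reals round-trip to at least
#' 1e-12).
#'
#' @param fit A `duet` fit object (see [duet()]).
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the vector of files written.
#' @export
save_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "duet"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  wtsv <- function(mat, name) {
    p <- file.path(out_dir, name)
    df <- data.frame(spot = rownames2(mat), format(mat, digits = 17,
                                                   scientific = TRUE,
                                                   trim = TRUE),
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wtsv(fit$Z, "Z.tsv")
  wtsv(fit$beta, "beta.tsv")
  for (m in names(fit$alpha))
    wtsv(fit$alpha[[m]], paste0("alpha_", m, ".tsv"))
  if (!is.null(fit$clusters)) {
    p <- file.path(out_dir, "clusters.tsv")
    utils::write.table(
      data.frame(spot = rownames2(fit$Z), cluster = fit$clusters),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "loss_trace.csv")
  utils::write.table(format(fit$loss_trace, digits = 17, trim = TRUE), p,
                     sep = ",", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(fit$config), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

rownames2 <- function(mat) {
  if (is.null(rownames(mat))) paste0("spot", seq_len(nrow(mat)))
  else rownames(mat)
}

#' Read back results written by [save_results()]
#'
#' @param out_dir Directory previously passed to [save_results()].
#' @return List with `Z`, `beta`, `alpha` (named list), `clusters` (or NULL),
#'   `loss_trace`, `config`.
#' @export
load_results <- function(out_dir) {
  rtsv <- function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    m
  }
  alpha_files <- list.files(out_dir, pattern = "^alpha_.*\\.tsv$",
                            full.names = TRUE)
  alpha <- lapply(alpha_files, rtsv)
  names(alpha) <- sub("^alpha_(.*)\\.tsv$", "\\1", basename(alpha_files))
  cl_path <- file.path(out_dir, "clusters.tsv")
  clusters <- if (file.exists(cl_path)) {
    utils::read.table(cl_path, header = TRUE, sep = "\t")$cluster
  }
  list(
    Z = rtsv(file.path(out_dir, "Z.tsv")),
    beta = rtsv(file.path(out_dir, "beta.tsv")),
    alpha = alpha,
    clusters = clusters,
    loss_trace = utils::read.table(file.path(out_dir, "loss_trace.csv"),
                                   header = TRUE, sep = ","),
    config = jsonlite::read_json(file.path(out_dir, "config.json"),
                                 simplifyVector = TRUE))
}
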