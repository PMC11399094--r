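#' Weighted reconstruction loss
#'
#' Sum over modalities of the weighted squared Frobenius distance between
#' each modality's processed input and its reconstruction:
#' `sum_m gamma_m ||H0_m - Hhat_m||_F^2`.
#'
#' @param H0_list,Hhat_list Lists of M matching spot-by-d matrices.
#' @param gamma_recon Length-M non-negative weights (recycled).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(H0_list, Hhat_list, gamma_recon = 1) {
  stopifnot(length(H0_list) == length(Hhat_list))
  g <- rep_len(gamma_recon, length(H0_list))
  loss <- 0
  for (m in seq_along(H0_list)) {
    if (!all(dim(H0_list[[m]]) == dim(Hhat_list[[m]])))
      stop("shape mismatch in modality ", m)
    loss <- loss + g[m] * sum((H0_list[[m]] - Hhat_list[[m]])^2)
  }
  loss
}

#' Weighted correspondence loss
#'
#' Same form as [reconstruction_loss()] but comparing each modality-specific
#' representation with its reconstruction through the other modality's
#' decoder-encoder.
#'
#' @param Y_list,Yhat_list Lists of M matching spot-by-d_latent matrices.
#' @param gamma_corr Length-M non-negative weights (recycled).
#' @return Scalar loss.
#' @export
correspondence_loss <- function(Y_list, Yhat_list, gamma_corr = 1) {
  reconstruction_loss(Y_list, Yhat_list, gamma_corr)
}

# One Adam step over a flat named parameter list. st holds m, v, t.
adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  list(params = params, st = st)
}

#' Train the dual-attention graph autoencoder
#'
#' Full-batch Adam on the total loss (reconstruction + correspondence) for
#' `config$epochs` steps. Deterministic given `config$seed` and a fixed
#' thread count. Most users should call [duet()], which wraps preprocessing,
#' graph construction, training and inference.
#'
#' @param dataset A `spatial_dataset` with `processed` inputs (see
#'   [prepare_inputs()]).
#' @param config A [duet_config()].
#' @param graphs Optional precomputed list `A_s`, `A_f_list` of normalised
#'   adjacencies; built from the dataset when NULL.
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return List with `state` (trained `duet_state`), `trace` (data.frame
#'   epoch/recon/corr/total), `forward` (inference-mode forward outputs) and
#'   `graphs`.
#' @export
train_model <- function(dataset, config = duet_config(), graphs = NULL,
                        verbose = 0L) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  H0_list <- lapply(dataset$modalities, function(m) {
    if (is.null(m$processed))
      stop("modality '", m$name, "' has no processed input; ",
           "run prepare_inputs() first")
    m$processed
  })
  M <- length(H0_list)
  d_in <- ncol(H0_list[[1]])
  if (is.null(graphs)) {
    A_s <- symmetric_normalize(
      build_spatial_graph(dataset$coordinates, config$r_spatial),
      config$add_self_loops)
    A_f_list <- lapply(H0_list, function(h)
      symmetric_normalize(build_feature_graph(h, config$k_feature),
                          config$add_self_loops))
    graphs <- list(A_s = A_s, A_f_list = A_f_list)
  }
  state <- init_model_state(M, d_in, config)
  st <- list(m = lapply(state$params, function(x) x * 0),
             v = lapply(state$params, function(x) x * 0), t = 0L)
  trace <- matrix(0, config$epochs, 3,
                  dimnames = list(NULL, c("recon", "corr", "total")))
  for (ep in seq_len(config$epochs)) {
    fb <- forward_backward(H0_list, graphs$A_s, graphs$A_f_list, state,
                           config$gamma_recon, config$gamma_corr)
    if (!is.finite(fb$loss_total))
      stop("non-finite loss at epoch ", ep,
           "; try a smaller learning_rate than ", config$learning_rate)
    trace[ep, ] <- c(fb$loss_recon, fb$loss_corr, fb$loss_total)
    upd <- adam_step(state$params, fb$grads, st, config$learning_rate)
    state$params <- upd$params
    st <- upd$st
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d: recon %.4f corr %.4f total %.4f",
                      ep, fb$loss_recon, fb$loss_corr, fb$loss_total))
  }
  fwd <- forward_pass(H0_list, graphs$A_s, graphs$A_f_list, state,
                      config$gamma_recon, config$gamma_corr)
  list(state = state,
       trace = data.frame(epoch = seq_len(config$epochs), trace),
       forward = fwd, graphs = graphs)
}

#' Fit the dual-attention spatial multi-omics integration model
#'
#' The main entry point: builds the spatial and per-modality feature graphs,
#' trains the dual-attention graph convolutional autoencoder, and returns
#' the joint spot embedding with per-spot attention weights. Preprocessing is
#' applied automatically when any modality lacks a processed input.
#' Optionally clusters the embedding into spatial domains.
#'
#' @param dataset A `spatial_dataset` (see [assemble_dataset()]).
#' @param config A [duet_config()] or a preset from [dataset_presets()].
#' @param n_clusters Optional number of spatial domains; when given, the
#'   embedding is clustered with [cluster_latent()].
#' @param cluster_method "gmm" (default) or "leiden".
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return Object of class `duet`: list with `Z` (spot-by-d_latent joint
#'   embedding), `alpha` (per-modality spot-by-2 within-modality weights),
#'   `beta` (spot-by-M between-modality weights), `clusters` (or NULL),
#'   `loss_trace`, `state`, `graphs`, `config`, `dataset`.
#' @examples
#' sim <- generate_benchmark("default", seed = 1, grid = c(12, 12))
#' cfg <- duet_config(epochs = 50, d_latent = 16, seed = 1)
#' fit <- duet(sim$dataset, cfg, n_clusters = 5)
#' head(fit$beta)
#' @export
duet <- function(dataset, config = duet_config(), n_clusters = NULL,
                 cluster_method = c("gmm", "leiden"), verbose = 0L) {
  cluster_method <- match.arg(cluster_method)
  if (any(vapply(dataset$modalities,
                 function(m) is.null(m$processed), TRUE)))
    dataset <- prepare_inputs(dataset, config)
  tr <- train_model(dataset, config, verbose = verbose)
  fwd <- tr$forward
  ids <- rownames(dataset$coordinates)
  rownames(fwd$Z) <- ids
  colnames(fwd$Z) <- paste0("latent", seq_len(ncol(fwd$Z)))
  alpha <- fwd$alpha
  names(alpha) <- names(dataset$modalities)
  beta <- fwd$beta
  colnames(beta) <- names(dataset$modalities)
  rownames(beta) <- ids
  fit <- structure(
    list(Z = fwd$Z, alpha = alpha, beta = beta, clusters = NULL,
         loss_trace = tr$trace, state = tr$state, graphs = tr$graphs,
         forward = fwd, config = config, dataset = dataset),
    class = "duet")
  if (!is.null(n_clusters))
    fit$clusters <- cluster_latent(fit$Z, n_clusters,
                                   method = cluster_method,
                                   seed = config$seed)
  fit
}
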