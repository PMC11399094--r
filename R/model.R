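# Dual-attention graph autoencoder: parameter container, forward pass and
# reverse-mode gradients, all in base R + sparse Matrix products.
#
# Parameters live in a flat named list:
#   We_<m>_<l>, be_<m>_<l>   encoder weight/bias, layer l of modality m
#   Wd_<m>_<l>, bd_<m>_<l>   decoder weight/bias
#   Wq_<m>, bq_<m>, q_<m>    within-modality attention (shared across the
#                            modality's two graph branches)
#   Wv, bv, v                between-modality attention (global)
#   Wc, bc                   concat-mode projection (only in that mode)

adj_mat <- function(a) {
  if (inherits(a, "normalized_adjacency")) a$matrix else a
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform weights, zero biases, seeded for reproducibility. Encoder
#' layer widths run `d_in, d_latent, ..., d_latent` and the decoder mirrors
#' them; attention transforms are square `d_latent x d_latent`.
#'
#' @param n_modalities Number of modalities M.
#' @param d_in Common encoder input dimension.
#' @param config A [duet_config()] (uses `d_latent`, `n_layers`, `seed`,
#'   `aggregation_mode`).
#' @return Object of class `duet_state`: list with `params` (flat named list)
#'   and `meta`.
#' @export
init_model_state <- function(n_modalities, d_in, config = duet_config()) {
  d3 <- config$d_latent
  L <- config$n_layers
  enc_dims <- c(d_in, rep(d3, L))
  dec_dims <- c(d3, rep(d3, L - 1), d_in)
  set.seed(config$seed)
  p <- list()
  for (m in seq_len(n_modalities)) {
    for (l in seq_len(L)) {
      p[[sprintf("We_%d_%d", m, l)]] <- glorot(enc_dims[l], enc_dims[l + 1])
      p[[sprintf("be_%d_%d", m, l)]] <- numeric(enc_dims[l + 1])
      p[[sprintf("Wd_%d_%d", m, l)]] <- glorot(dec_dims[l], dec_dims[l + 1])
      p[[sprintf("bd_%d_%d", m, l)]] <- numeric(dec_dims[l + 1])
    }
    if (config$aggregation_mode == "attention") {
      p[[sprintf("Wq_%d", m)]] <- glorot(d3, d3)
      p[[sprintf("bq_%d", m)]] <- numeric(d3)
      p[[sprintf("q_%d", m)]] <- drop(glorot(d3, 1))
    }
  }
  if (config$aggregation_mode == "attention") {
    p$Wv <- glorot(d3, d3)
    p$bv <- numeric(d3)
    p$v <- drop(glorot(d3, 1))
  } else if (config$aggregation_mode == "concat") {
    p$Wc <- glorot(n_modalities * d3, d3)
    p$bc <- numeric(d3)
  }
  structure(list(params = p,
                 meta = list(M = n_modalities, d_in = d_in, d3 = d3, L = L,
                             mode = config$aggregation_mode,
                             final_activation = config$final_activation)),
            class = "duet_state")
}

## ---- graph convolution -----------------------------------------------------

gc_fwd <- function(A, H, W, b, act) {
  AH <- as.matrix(A %*% H)
  pre <- AH %*% W
  pre <- sweep(pre, 2, b, `+`)
  out <- if (act == "relu") pmax(pre, 0) else pre
  list(out = out, AH = AH,
       mask = if (act == "relu") pre > 0 else NULL)
}

gc_bwd <- function(A, W, cache, d_out) {
  d_pre <- if (is.null(cache$mask)) d_out else d_out * cache$mask
  list(dW = crossprod(cache$AH, d_pre),
       db = colSums(d_pre),
       dH = as.matrix(A %*% (d_pre %*% t(W))))  # A is symmetric
}

#' Single graph convolution layer
#'
#' Computes `activation(A_norm H W + b)` with the bias broadcast over spots.
#'
#' @param H Spot-by-p input matrix.
#' @param A_norm A [symmetric_normalize()] result or an N x N matrix.
#' @param W p-by-q weight matrix.
#' @param b Length-q bias vector.
#' @param activation "identity" or "relu".
#' @return Spot-by-q matrix.
#' @export
graph_conv <- function(H, A_norm, W, b = numeric(ncol(W)),
                       activation = c("identity", "relu")) {
  activation <- match.arg(activation)
  H <- as.matrix(H)
  if (ncol(H) != nrow(W)) stop("ncol(H) != nrow(W)")
  if (length(b) != ncol(W)) stop("bias length != ncol(W)")
  gc_fwd(adj_mat(A_norm), H, W, b, activation)$out
}

# Multi-layer stack; weights/biases are lists of length L. Hidden layers
# ReLU, last layer `final_act`.
stack_fwd <- function(A, H0, Ws, bs, final_act) {
  L <- length(Ws)
  caches <- vector("list", L)
  h <- H0
  for (l in seq_len(L)) {
    act <- if (l < L) "relu" else final_act
    c_l <- gc_fwd(A, h, Ws[[l]], bs[[l]], act)
    caches[[l]] <- c_l
    h <- c_l$out
  }
  list(out = h, caches = caches)
}

stack_bwd <- function(A, Ws, caches, d_out) {
  L <- length(Ws)
  dW <- vector("list", L)
  db <- vector("list", L)
  d <- d_out
  for (l in rev(seq_len(L))) {
    g <- gc_bwd(A, Ws[[l]], caches[[l]], d)
    dW[[l]] <- g$dW
    db[[l]] <- g$db
    d <- g$dH
  }
  list(dW = dW, db = db, dH0 = d)
}

#' Encode one modality over its two graphs
#'
#' Runs the modality's shared encoder stack once on the spatial graph and
#' once on the feature graph, producing the two graph-specific
#' representations.
#'
#' @param H0 Spot-by-d_in processed input.
#' @param A_s_norm,A_f_norm Normalised spatial and feature adjacencies.
#' @param We,be Lists of layer weights/biases (length L).
#' @param final_activation Activation of the last layer ("identity" default).
#' @return List `H_s`, `H_f` (spot-by-d_latent matrices).
#' @export
encode_modality <- function(H0, A_s_norm, A_f_norm, We, be,
                            final_activation = "identity") {
  if (is.matrix(We)) { We <- list(We); be <- list(be) }
  list(H_s = stack_fwd(adj_mat(A_s_norm), as.matrix(H0), We, be,
                       final_activation)$out,
       H_f = stack_fwd(adj_mat(A_f_norm), as.matrix(H0), We, be,
                       final_activation)$out)
}

#' Decode the joint embedding back to one modality's input space
#'
#' Graph convolution stack on the spatial graph mapping the joint latent Z to
#' a reconstruction of the modality's processed input; the final layer is
#' linear so signed targets are reachable.
#'
#' @param Z Spot-by-d_latent joint embedding.
#' @param A_s_norm Normalised spatial adjacency.
#' @param Wd,bd Lists of decoder layer weights/biases.
#' @param final_activation Activation of the last layer.
#' @return Spot-by-d_in reconstruction.
#' @export
decode_modality <- function(Z, A_s_norm, Wd, bd,
                            final_activation = "identity") {
  if (is.matrix(Wd)) { Wd <- list(Wd); bd <- list(bd) }
  stack_fwd(adj_mat(A_s_norm), as.matrix(Z), Wd, bd, final_activation)$out
}

## ---- attention aggregation -------------------------------------------------

# Softmax-weighted aggregation over a list of T representations using shared
# parameters (W, b, q). Used both within modalities (T = 2 graphs) and
# between modalities (T = M).
att_fwd <- function(H_list, W, b, q) {
  T_ <- length(H_list)
  n <- nrow(H_list[[1]])
  U <- vector("list", T_)
  e <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    U[[t]] <- tanh(sweep(H_list[[t]] %*% W, 2, b, `+`))
    e[, t] <- U[[t]] %*% q
  }
  e_max <- apply(e, 1, max)
  ex <- exp(e - e_max)
  alpha <- ex / rowSums(ex)
  Y <- matrix(0, n, ncol(H_list[[1]]))
  for (t in seq_len(T_)) Y <- Y + alpha[, t] * H_list[[t]]
  list(Y = Y, alpha = alpha, U = U, H_list = H_list)
}

att_bwd <- function(cache, W, q, dY) {
  T_ <- length(cache$H_list)
  alpha <- cache$alpha
  dalpha <- matrix(0, nrow(alpha), T_)
  dH <- vector("list", T_)
  for (t in seq_len(T_)) {
    dH[[t]] <- alpha[, t] * dY
    dalpha[, t] <- rowSums(dY * cache$H_list[[t]])
  }
  s <- rowSums(alpha * dalpha)
  de <- alpha * (dalpha - s)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  dq <- numeric(length(q))
  for (t in seq_len(T_)) {
    U <- cache$U[[t]]
    dU <- tcrossprod(de[, t], q)          # outer(de_t, q)
    dq <- dq + drop(crossprod(U, de[, t]))
    dP <- dU * (1 - U * U)
    dW <- dW + crossprod(cache$H_list[[t]], dP)
    db <- db + colSums(dP)
    dH[[t]] <- dH[[t]] + dP %*% t(W)
  }
  list(dH = dH, dW = dW, db = db, dq = dq)
}

mean_fwd <- function(H_list) {
  T_ <- length(H_list)
  Y <- Reduce(`+`, H_list) / T_
  list(Y = Y, alpha = matrix(1 / T_, nrow(Y), T_), H_list = H_list)
}

#' Within-modality attention aggregation
#'
#' Scores each graph-specific representation per spot with
#' `e = q' tanh(W h + b)`, softmaxes over the graphs and returns the
#' weighted combination.
#'
#' @param H_s,H_f Spot-by-d_latent representations from the spatial and
#'   feature graphs.
#' @param W,b,q Shared attention parameters (square W, bias b, score vector
#'   q).
#' @return List `Y` (aggregated representation) and `alpha` (spot-by-2 weight
#'   matrix, rows sum to 1; columns "spatial", "feature").
#' @export
within_attention <- function(H_s, H_f, W, b, q) {
  f <- att_fwd(list(as.matrix(H_s), as.matrix(H_f)), W, b, q)
  colnames(f$alpha) <- c("spatial", "feature")
  list(Y = f$Y, alpha = f$alpha)
}

#' Between-modality attention aggregation
#'
#' Same scoring as [within_attention()] but across the M modality-specific
#' representations; works for any M >= 1.
#'
#' @param Y_list List of M spot-by-d_latent matrices.
#' @param W,b,v Global attention parameters.
#' @return List `Z` (joint embedding) and `beta` (spot-by-M weights, rows sum
#'   to 1).
#' @export
between_attention <- function(Y_list, W, b, v) {
  f <- att_fwd(lapply(Y_list, as.matrix), W, b, v)
  list(Z = f$Y, beta = f$alpha)
}

#' Cross-modality correspondence path
#'
#' Sends a modality-specific representation through another modality's
#' decoder and encoder (both on the spatial graph), yielding the
#' representation whose agreement with the original the correspondence loss
#' enforces.
#'
#' @param Y Spot-by-d_latent representation of one modality.
#' @param A_s_norm Normalised spatial adjacency.
#' @param Wd,bd,We,be The other modality's decoder and encoder stacks.
#' @param final_activation Activation of each stack's last layer.
#' @return Spot-by-d_latent matrix.
#' @export
correspondence_path <- function(Y, A_s_norm, Wd, bd, We, be,
                                final_activation = "identity") {
  if (is.matrix(Wd)) { Wd <- list(Wd); bd <- list(bd) }
  if (is.matrix(We)) { We <- list(We); be <- list(be) }
  A <- adj_mat(A_s_norm)
  d <- stack_fwd(A, as.matrix(Y), Wd, bd, final_activation)$out
  stack_fwd(A, d, We, be, final_activation)$out
}

## ---- full forward / backward ----------------------------------------------

param_lists <- function(p, prefix, m, L) {
  W <- lapply(seq_len(L), function(l) p[[sprintf("W%s_%d_%d", prefix, m, l)]])
  b <- lapply(seq_len(L), function(l) p[[sprintf("b%s_%d_%d", prefix, m, l)]])
  list(W = W, b = b)
}

#' Full model forward pass
#'
#' Composes encoding, within- and between-modality attention, decoding and
#' the correspondence paths for all modalities, and evaluates both losses.
#'
#' @param H0_list List of M spot-by-d_in processed inputs.
#' @param A_s Normalised spatial adjacency.
#' @param A_f_list List of M normalised feature adjacencies.
#' @param state A `duet_state`.
#' @param gamma_recon,gamma_corr Loss weights (length M, recycled).
#' @return List with `Z`, `beta`, `alpha` (list), `Y` (list), `H_s`, `H_f`,
#'   `H_hat` (reconstructions), `Y_hat` (correspondence outputs),
#'   `loss_recon`, `loss_corr`, `loss_total`.
#' @export
forward_pass <- function(H0_list, A_s, A_f_list, state,
                         gamma_recon = 1, gamma_corr = 1) {
  fb <- forward_backward(H0_list, A_s, A_f_list, state,
                         gamma_recon, gamma_corr, want_grads = FALSE)
  fb[c("Z", "beta", "alpha", "Y", "H_s", "H_f", "H_hat", "Y_hat",
       "loss_recon", "loss_corr", "loss_total")]
}

# Forward pass with optional reverse-mode gradients for every parameter.
# Returns outputs, losses and (when want_grads) a flat named list `grads`
# aligned with state$params.
forward_backward <- function(H0_list, A_s, A_f_list, state,
                             gamma_recon = 1, gamma_corr = 1,
                             want_grads = TRUE) {
  meta <- state$meta
  p <- state$params
  M <- meta$M
  L <- meta$L
  fact <- meta$final_activation
  stopifnot(length(H0_list) == M, length(A_f_list) == M)
  As <- adj_mat(A_s)
  Af <- lapply(A_f_list, adj_mat)
  gr <- rep_len(gamma_recon, M)
  gc_ <- rep_len(gamma_corr, M)
  H0_list <- lapply(H0_list, as.matrix)
  n <- nrow(H0_list[[1]])

  enc <- lapply(seq_len(M), function(m) param_lists(p, "e", m, L))
  dec <- lapply(seq_len(M), function(m) param_lists(p, "d", m, L))

  # encoders on both graphs (shared weights per modality)
  f_s <- vector("list", M); f_f <- vector("list", M)
  wa <- vector("list", M)
  Y <- vector("list", M)
  for (m in seq_len(M)) {
    f_s[[m]] <- stack_fwd(As, H0_list[[m]], enc[[m]]$W, enc[[m]]$b, fact)
    f_f[[m]] <- stack_fwd(Af[[m]], H0_list[[m]], enc[[m]]$W, enc[[m]]$b, fact)
    branches <- list(f_s[[m]]$out, f_f[[m]]$out)
    wa[[m]] <- if (meta$mode == "attention") {
      att_fwd(branches, p[[sprintf("Wq_%d", m)]], p[[sprintf("bq_%d", m)]],
              p[[sprintf("q_%d", m)]])
    } else mean_fwd(branches)
    colnames(wa[[m]]$alpha) <- c("spatial", "feature")
    Y[[m]] <- wa[[m]]$Y
  }

  # between-modality aggregation
  if (meta$mode == "attention") {
    ba <- att_fwd(Y, p$Wv, p$bv, p$v)
    Z <- ba$Y; beta <- ba$alpha
  } else if (meta$mode == "mean") {
    ba <- mean_fwd(Y)
    Z <- ba$Y; beta <- ba$alpha
  } else {  # concat: learned projection, uniform weights reported
    Ycat <- do.call(cbind, Y)
    Z <- sweep(Ycat %*% p$Wc, 2, p$bc, `+`)
    beta <- matrix(1 / M, n, M)
  }

  # decoders and correspondence paths
  f_dec <- vector("list", M)
  H_hat <- vector("list", M)
  f_cd <- vector("list", M)   # decoder of 'nxt' applied to Y_m
  f_ce <- vector("list", M)   # encoder of 'nxt' applied to that
  Y_hat <- vector("list", M)
  for (m in seq_len(M)) {
    f_dec[[m]] <- stack_fwd(As, Z, dec[[m]]$W, dec[[m]]$b, fact)
    H_hat[[m]] <- f_dec[[m]]$out
    nxt <- m %% M + 1L
    f_cd[[m]] <- stack_fwd(As, Y[[m]], dec[[nxt]]$W, dec[[nxt]]$b, fact)
    f_ce[[m]] <- stack_fwd(As, f_cd[[m]]$out, enc[[nxt]]$W, enc[[nxt]]$b,
                           fact)
    Y_hat[[m]] <- f_ce[[m]]$out
  }

  loss_recon <- 0; loss_corr <- 0
  R <- vector("list", M); C <- vector("list", M)
  for (m in seq_len(M)) {
    R[[m]] <- H_hat[[m]] - H0_list[[m]]
    C[[m]] <- Y[[m]] - Y_hat[[m]]
    loss_recon <- loss_recon + gr[m] * sum(R[[m]]^2)
    loss_corr <- loss_corr + gc_[m] * sum(C[[m]]^2)
  }

  out <- list(Z = Z, beta = beta,
              alpha = lapply(wa, `[[`, "alpha"),
              Y = Y,
              H_s = lapply(f_s, `[[`, "out"),
              H_f = lapply(f_f, `[[`, "out"),
              H_hat = H_hat, Y_hat = Y_hat,
              loss_recon = loss_recon, loss_corr = loss_corr,
              loss_total = loss_recon + loss_corr)
  if (!want_grads) return(out)

  g <- lapply(seq_along(p), function(i) {
    if (is.matrix(p[[i]])) matrix(0, nrow(p[[i]]), ncol(p[[i]]))
    else numeric(length(p[[i]]))
  })
  names(g) <- names(p)
  add <- function(key, d) g[[key]] <<- g[[key]] + d

  dZ <- matrix(0, n, meta$d3)
  dY <- lapply(seq_len(M), function(m) matrix(0, n, meta$d3))

  for (m in seq_len(M)) {
    # reconstruction branch
    bw <- stack_bwd(As, dec[[m]]$W, f_dec[[m]]$caches, 2 * gr[m] * R[[m]])
    for (l in seq_len(L)) {
      add(sprintf("Wd_%d_%d", m, l), bw$dW[[l]])
      add(sprintf("bd_%d_%d", m, l), bw$db[[l]])
    }
    dZ <- dZ + bw$dH0
    # correspondence branch: direct term on Y_m, path term through 'nxt'
    dY[[m]] <- dY[[m]] + 2 * gc_[m] * C[[m]]
    nxt <- m %% M + 1L
    bw_e <- stack_bwd(As, enc[[nxt]]$W, f_ce[[m]]$caches,
                      -2 * gc_[m] * C[[m]])
    for (l in seq_len(L)) {
      add(sprintf("We_%d_%d", nxt, l), bw_e$dW[[l]])
      add(sprintf("be_%d_%d", nxt, l), bw_e$db[[l]])
    }
    bw_d <- stack_bwd(As, dec[[nxt]]$W, f_cd[[m]]$caches, bw_e$dH0)
    for (l in seq_len(L)) {
      add(sprintf("Wd_%d_%d", nxt, l), bw_d$dW[[l]])
      add(sprintf("bd_%d_%d", nxt, l), bw_d$db[[l]])
    }
    dY[[m]] <- dY[[m]] + bw_d$dH0
  }

  # between-modality aggregation backward
  if (meta$mode == "attention") {
    bwb <- att_bwd(ba, p$Wv, p$v, dZ)
    add("Wv", bwb$dW); add("bv", bwb$db); add("v", bwb$dq)
    for (m in seq_len(M)) dY[[m]] <- dY[[m]] + bwb$dH[[m]]
  } else if (meta$mode == "mean") {
    for (m in seq_len(M)) dY[[m]] <- dY[[m]] + dZ / M
  } else {
    Ycat <- do.call(cbind, Y)
    add("Wc", crossprod(Ycat, dZ))
    add("bc", colSums(dZ))
    dYcat <- dZ %*% t(p$Wc)
    for (m in seq_len(M))
      dY[[m]] <- dY[[m]] + dYcat[, (m - 1) * meta$d3 + seq_len(meta$d3),
                                 drop = FALSE]
  }

  # within-modality aggregation and encoder backward
  for (m in seq_len(M)) {
    if (meta$mode == "attention") {
      bwa <- att_bwd(wa[[m]], p[[sprintf("Wq_%d", m)]],
                     p[[sprintf("q_%d", m)]], dY[[m]])
      add(sprintf("Wq_%d", m), bwa$dW)
      add(sprintf("bq_%d", m), bwa$db)
      add(sprintf("q_%d", m), bwa$dq)
      dHs <- bwa$dH[[1]]; dHf <- bwa$dH[[2]]
    } else {
      dHs <- dY[[m]] / 2; dHf <- dY[[m]] / 2
    }
    bs <- stack_bwd(As, enc[[m]]$W, f_s[[m]]$caches, dHs)
    bf <- stack_bwd(Af[[m]], enc[[m]]$W, f_f[[m]]$caches, dHf)
    for (l in seq_len(L)) {
      add(sprintf("We_%d_%d", m, l), bs$dW[[l]] + bf$dW[[l]])
      add(sprintf("be_%d_%d", m, l), bs$db[[l]] + bf$db[[l]])
    }
  }

  out$grads <- g
  out
}
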