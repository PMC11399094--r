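# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorised/sparse code paths: explicit loops, dense
# matrices, per-spot arithmetic.

# triple-loop dense graph convolution: act(A H W + b)
oracle_graph_conv <- function(A, H, W, b, act = "identity") {
  A <- as.matrix(A); H <- as.matrix(H)
  n <- nrow(H); q <- ncol(W)
  out <- matrix(0, n, q)
  for (i in seq_len(n)) {
    for (jj in seq_len(q)) {
      acc <- 0
      for (k in seq_len(n)) {
        for (p in seq_len(ncol(H))) {
          acc <- acc + A[i, k] * H[k, p] * W[p, jj]
        }
      }
      acc <- acc + b[jj]
      out[i, jj] <- if (act == "relu") max(acc, 0) else acc
    }
  }
  out
}

# per-spot attention aggregation: e_t = q' tanh(W h_t + b), softmax, combine
oracle_attention <- function(H_list, W, b, q) {
  n <- nrow(H_list[[1]]); T_ <- length(H_list)
  Y <- matrix(0, n, ncol(H_list[[1]]))
  alpha <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    e <- numeric(T_)
    for (t in seq_len(T_)) {
      h <- H_list[[t]][i, ]
      e[t] <- sum(q * tanh(as.numeric(W %*% h) + b))
    }
    a <- exp(e - max(e)); a <- a / sum(a)
    alpha[i, ] <- a
    for (t in seq_len(T_)) Y[i, ] <- Y[i, ] + a[t] * H_list[[t]][i, ]
  }
  list(Y = Y, alpha = alpha)
}

# Note: the model computes tanh(H %*% W + b) with W applied on the right;
# the oracle above must see the transposed weight to describe the same map.
oracle_attention_rowform <- function(H_list, W, b, q) {
  oracle_attention(H_list, t(W), b, q)
}

# brute-force exact KNN with ties to the smaller index, OR-symmetrised
oracle_knn_adjacency <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))  # ties -> smaller index
    A[i, ord[seq_len(k)]] <- 1
  }
  pmax(A, t(A))
}

# pair-counting Rand statistics and entropy-based scores (no AMI here; the
# adjusted score's expected-MI term is checked against frozen external
# reference values instead)
oracle_pair_scores <- function(truth, pred) {
  n <- length(truth)
  same_t <- outer(truth, truth, `==`)
  same_p <- outer(pred, pred, `==`)
  ut <- upper.tri(same_t)
  a <- sum(same_t[ut] & same_p[ut])
  b <- sum(!same_t[ut] & !same_p[ut])
  n_pairs <- n * (n - 1) / 2
  ri <- (a + b) / n_pairs
  # expected/max index for the adjustment
  sum_t <- sum(choose(table(truth), 2))
  sum_p <- sum(choose(table(pred), 2))
  exp_i <- sum_t * sum_p / n_pairs
  max_i <- (sum_t + sum_p) / 2
  ari <- if (max_i == exp_i) 1 else (a - exp_i) / (max_i - exp_i)
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  mi <- 0
  for (tv in unique(truth)) for (pv in unique(pred)) {
    pij <- mean(truth == tv & pred == pv)
    if (pij > 0)
      mi <- mi + pij * log(pij / (mean(truth == tv) * mean(pred == pv)))
  }
  h_t <- ent(truth); h_p <- ent(pred)
  hom <- if (h_t == 0) 1 else mi / h_t
  com <- if (h_p == 0) 1 else mi / h_p
  v <- if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  nmi <- if (h_t + h_p == 0) 1 else mi / ((h_t + h_p) / 2)
  c(homogeneity = hom, mutual_information = mi, v_measure = v,
    NMI = nmi, ARI = ari, rand = ri)
}

# double-loop Moran's I for one indicator vector over a weight matrix
oracle_morans_i <- function(x, w) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * xc[i] * xc[j]
  (n / sum(w)) * num / sum(xc^2)
}

# small random multi-modality instance with graphs, used by model tests
make_toy_instance <- function(n = 8, d_in = 3, M = 2, d3 = 4, L = 1,
                              seed = 1, mode = "attention",
                              perturb = 0) {
  set.seed(seed)
  coords <- matrix(stats::runif(n * 2), n, 2)
  H0 <- lapply(seq_len(M), function(m) matrix(stats::rnorm(n * d_in), n, d_in))
  cfg <- duet_config(d_latent = d3, n_layers = L, seed = seed + 1,
                     r_spatial = 2, k_feature = 2,
                     aggregation_mode = mode)
  A_s <- symmetric_normalize(build_spatial_graph(coords, 2))
  A_f <- lapply(H0, function(h) symmetric_normalize(build_feature_graph(h, 2)))
  state <- init_model_state(M, d_in, cfg)
  if (perturb > 0)
    state$params <- lapply(state$params,
                           function(p) p + stats::rnorm(length(p), 0, perturb))
  list(n = n, coords = coords, H0 = H0, A_s = A_s, A_f = A_f,
       state = state, cfg = cfg)
}

# tiny labelled benchmark for pipeline tests (coarse grid, quick to fit)
make_tiny_benchmark <- function(seed = 1, grid = c(12, 12)) {
  generate_benchmark("default", seed = seed, grid = grid)
}
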