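test_that("graph_conv reduces to known closed forms", {
  set.seed(31)
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(graph_conv(H, diag(4), diag(3)), H)
  b <- c(1, -2)
  expect_equal(graph_conv(H, diag(4), matrix(0, 3, 2), b),
               matrix(b, 4, 2, byrow = TRUE))
  expect_equal(graph_conv(H, diag(4), matrix(0, 3, 2), b, "relu"),
               matrix(pmax(b, 0), 4, 2, byrow = TRUE))
})

test_that("graph_conv matches the triple-loop dense oracle", {
  set.seed(32)
  for (act in c("identity", "relu")) {
    A <- as.matrix(symmetric_normalize(
      build_spatial_graph(matrix(runif(10), 5, 2), 2))$matrix)
    H <- matrix(rnorm(5 * 3), 5, 3)
    W <- matrix(rnorm(3 * 4), 3, 4)
    b <- rnorm(4)
    expect_equal(graph_conv(H, A, W, b, act),
                 oracle_graph_conv(A, H, W, b, act), tolerance = 1e-6)
  }
})

test_that("encoder branches coincide when both graphs coincide", {
  toy <- make_toy_instance(seed = 33)
  p <- toy$state$params
  enc <- encode_modality(toy$H0[[1]], toy$A_s, toy$A_s,
                         p$We_1_1, p$be_1_1)
  expect_identical(enc$H_s, enc$H_f)
})

test_that("single-layer encoder equals the dense closed form", {
  toy <- make_toy_instance(seed = 34)
  p <- toy$state$params
  A <- as.matrix(toy$A_s$matrix)
  enc <- encode_modality(toy$H0[[1]], toy$A_s, toy$A_f[[1]],
                         p$We_1_1, p$be_1_1)
  hand <- sweep(A %*% toy$H0[[1]] %*% p$We_1_1, 2, p$be_1_1, `+`)
  expect_equal(enc$H_s, hand, tolerance = 1e-10)
})

test_that("within-modality attention honours symmetry and hand arithmetic", {
  set.seed(35)
  H <- matrix(rnorm(6 * 4), 6, 4)
  W <- matrix(rnorm(16), 4, 4); b <- rnorm(4); q <- rnorm(4)
  wa <- within_attention(H, H, W, b, q)
  expect_equal(unname(wa$alpha), matrix(0.5, 6, 2))
  expect_equal(wa$Y, H)
  # hand-evaluated scalar chain at d3 = 2
  h_s <- matrix(c(1, 0), 1, 2)
  h_f <- matrix(c(0, 1), 1, 2)
  wa2 <- within_attention(h_s, h_f, diag(2), c(0, 0), c(1, 0))
  e_s <- tanh(1); e_f <- tanh(0)
  a_s <- exp(e_s) / (exp(e_s) + exp(e_f))
  expect_equal(unname(wa2$alpha), matrix(c(a_s, 1 - a_s), 1, 2))
  expect_equal(unname(wa2$Y), a_s * h_s + (1 - a_s) * h_f)
})

test_that("within attention matches the per-spot oracle", {
  set.seed(36)
  H_s <- matrix(rnorm(7 * 3), 7, 3)
  H_f <- matrix(rnorm(7 * 3), 7, 3)
  W <- matrix(rnorm(9), 3, 3); b <- rnorm(3); q <- rnorm(3)
  wa <- within_attention(H_s, H_f, W, b, q)
  orc <- oracle_attention_rowform(list(H_s, H_f), W, b, q)
  expect_equal(wa$Y, orc$Y, tolerance = 1e-6)
  expect_equal(unname(wa$alpha), orc$alpha, tolerance = 1e-6)
})

test_that("between-modality attention handles M = 1, symmetry and M = 3", {
  set.seed(37)
  Y1 <- matrix(rnorm(5 * 3), 5, 3)
  W <- matrix(rnorm(9), 3, 3); b <- rnorm(3); v <- rnorm(3)
  ba1 <- between_attention(list(Y1), W, b, v)
  expect_equal(unname(ba1$beta), matrix(1, 5, 1))
  expect_equal(ba1$Z, Y1)
  ba2 <- between_attention(list(Y1, Y1), W, b, v)
  expect_equal(unname(ba2$beta), matrix(0.5, 5, 2))
  expect_equal(ba2$Z, Y1)
  Ys <- list(Y1, matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  ba3 <- between_attention(Ys, W, b, v)
  orc <- oracle_attention_rowform(Ys, W, b, v)
  expect_equal(ba3$Z, orc$Y, tolerance = 1e-6)
  expect_equal(unname(ba3$beta), orc$alpha, tolerance = 1e-6)
})

test_that("decoder reduces to closed forms and the dense oracle", {
  set.seed(38)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  Wd <- matrix(rnorm(4 * 3), 4, 3); bd <- rnorm(3)
  expect_equal(decode_modality(matrix(0, 6, 4), diag(6), Wd, numeric(3)),
               matrix(0, 6, 3))
  expect_equal(decode_modality(Z, diag(6), Wd, bd),
               sweep(Z %*% Wd, 2, bd, `+`))
  A <- as.matrix(symmetric_normalize(
    build_spatial_graph(matrix(runif(12), 6, 2), 2))$matrix)
  expect_equal(decode_modality(Z, A, Wd, bd),
               oracle_graph_conv(A, Z, Wd, bd), tolerance = 1e-6)
})

test_that("correspondence path composes decoder and encoder", {
  set.seed(39)
  Y <- matrix(rnorm(5 * 3), 5, 3)
  # identity weights and identity graph reproduce Y
  expect_equal(correspondence_path(Y, diag(5), diag(3), numeric(3),
                                   diag(3), numeric(3)), Y)
  Wd <- matrix(rnorm(3 * 4), 3, 4); bd <- rnorm(4)
  We <- matrix(rnorm(4 * 3), 4, 3); be <- rnorm(3)
  A <- as.matrix(symmetric_normalize(
    build_spatial_graph(matrix(runif(10), 5, 2), 2))$matrix)
  got <- correspondence_path(Y, A, Wd, bd, We, be)
  orc <- oracle_graph_conv(A, oracle_graph_conv(A, Y, Wd, bd), We, be)
  expect_equal(got, orc, tolerance = 1e-6)
  expect_equal(dim(got), dim(Y))
})

test_that("the composed forward pass equals the per-layer oracle chain", {
  toy <- make_toy_instance(n = 20, d_in = 3, d3 = 4, seed = 40,
                           perturb = 0.1)
  p <- toy$state$params
  fwd <- forward_pass(toy$H0, toy$A_s, toy$A_f, toy$state,
                      gamma_recon = c(1, 2), gamma_corr = c(3, 0.5))
  A_s <- as.matrix(toy$A_s$matrix)
  A_f <- lapply(toy$A_f, function(a) as.matrix(a$matrix))
  Y <- vector("list", 2)
  for (m in 1:2) {
    We <- p[[sprintf("We_%d_1", m)]]; be <- p[[sprintf("be_%d_1", m)]]
    Hs <- oracle_graph_conv(A_s, toy$H0[[m]], We, be)
    Hf <- oracle_graph_conv(A_f[[m]], toy$H0[[m]], We, be)
    wa <- oracle_attention_rowform(list(Hs, Hf), p[[sprintf("Wq_%d", m)]],
                                   p[[sprintf("bq_%d", m)]],
                                   p[[sprintf("q_%d", m)]])
    Y[[m]] <- wa$Y
    expect_equal(fwd$alpha[[m]], wa$alpha, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  ba <- oracle_attention_rowform(Y, p$Wv, p$bv, p$v)
  expect_equal(fwd$Z, ba$Y, tolerance = 1e-6)
  expect_equal(unname(fwd$beta), ba$alpha, tolerance = 1e-6)
  # reconstructions and correspondence outputs
  recon <- corr <- 0
  gr <- c(1, 2); gc_ <- c(3, 0.5)
  for (m in 1:2) {
    Wd <- p[[sprintf("Wd_%d_1", m)]]; bd <- p[[sprintf("bd_%d_1", m)]]
    Hhat <- oracle_graph_conv(A_s, ba$Y, Wd, bd)
    expect_equal(fwd$H_hat[[m]], Hhat, tolerance = 1e-6)
    nxt <- m %% 2 + 1
    Yhat <- oracle_graph_conv(
      A_s,
      oracle_graph_conv(A_s, Y[[m]], p[[sprintf("Wd_%d_1", nxt)]],
                        p[[sprintf("bd_%d_1", nxt)]]),
      p[[sprintf("We_%d_1", nxt)]], p[[sprintf("be_%d_1", nxt)]])
    expect_equal(fwd$Y_hat[[m]], Yhat, tolerance = 1e-6)
    recon <- recon + gr[m] * sum((toy$H0[[m]] - Hhat)^2)
    corr <- corr + gc_[m] * sum((Y[[m]] - Yhat)^2)
  }
  expect_equal(fwd$loss_recon, recon, tolerance = 1e-6)
  expect_equal(fwd$loss_corr, corr, tolerance = 1e-6)
})

test_that("attention weights are simplex-valued and Z is in the Y envelope", {
  set.seed(41)
  n_trials <- 1000
  for (trial in seq_len(n_trials)) {
    n <- sample(4:8, 1)
    M <- sample(2:3, 1)
    d3 <- sample(2:4, 1)
    Ys <- lapply(seq_len(M), function(m) matrix(rnorm(n * d3, sd = 2), n, d3))
    W <- matrix(rnorm(d3 * d3), d3, d3); b <- rnorm(d3); v <- rnorm(d3)
    ba <- between_attention(Ys, W, b, v)
    expect_true(all(abs(rowSums(ba$beta) - 1) < 1e-6))
    expect_true(all(ba$beta >= 0))
    lo <- Reduce(pmin, Ys); hi <- Reduce(pmax, Ys)
    expect_true(all(ba$Z >= lo - 1e-9 & ba$Z <= hi + 1e-9))
  }
})

test_that("forward outputs are permutation-equivariant", {
  toy <- make_toy_instance(n = 12, seed = 42, perturb = 0.05)
  fwd <- forward_pass(toy$H0, toy$A_s, toy$A_f, toy$state)
  perm <- sample(12)
  pm <- function(A) {
    m <- as.matrix(A$matrix)[perm, perm]
    structure(list(matrix = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                        "CsparseMatrix"),
                   self_loops = TRUE), class = "normalized_adjacency")
  }
  fwd_p <- forward_pass(lapply(toy$H0, function(h) h[perm, ]),
                        pm(toy$A_s), lapply(toy$A_f, pm), toy$state)
  expect_equal(fwd_p$Z, fwd$Z[perm, ], tolerance = 1e-10)
  expect_equal(unname(fwd_p$beta), unname(fwd$beta[perm, ]),
               tolerance = 1e-10)
})

test_that("mean aggregation agrees with attention under branch symmetry", {
  toy_a <- make_toy_instance(seed = 43, mode = "attention")
  toy_m <- make_toy_instance(seed = 43, mode = "mean")
  # identical inputs for both modalities and identical graphs everywhere
  # (feature graph = spatial graph): H_s = H_f so alpha plays no role, and
  # Y1 = Y2 so beta plays no role -- both modes return Z = Y1
  H0 <- list(toy_a$H0[[1]], toy_a$H0[[1]])
  Af <- list(toy_a$A_s, toy_a$A_s)
  st_a <- toy_a$state
  # tie modality parameters together
  for (k in grep("_2", names(st_a$params), value = TRUE))
    st_a$params[[k]] <- st_a$params[[sub("_2", "_1", k)]]
  st_m <- toy_m$state
  for (k in grep("_2", names(st_m$params), value = TRUE))
    st_m$params[[k]] <- st_m$params[[sub("_2", "_1", k)]]
  for (k in intersect(names(st_m$params), names(st_a$params)))
    st_m$params[[k]] <- st_a$params[[k]]
  f_a <- forward_pass(H0, toy_a$A_s, Af, st_a)
  f_m <- forward_pass(H0, toy_a$A_s, Af, st_m)
  expect_equal(unname(f_a$beta), matrix(0.5, toy_a$n, 2), tolerance = 1e-12)
  expect_equal(f_a$Z, f_m$Z, tolerance = 1e-10)
})

test_that("concat aggregation projects the concatenated representations", {
  toy <- make_toy_instance(seed = 44, mode = "concat", perturb = 0.05)
  fwd <- forward_pass(toy$H0, toy$A_s, toy$A_f, toy$state)
  p <- toy$state$params
  Ycat <- do.call(cbind, fwd$Y)
  expect_equal(fwd$Z, sweep(Ycat %*% p$Wc, 2, p$bc, `+`), tolerance = 1e-10)
})
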