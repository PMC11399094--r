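test_that("loss functions reduce to hand-computed sums", {
  H0 <- list(matrix(1:6, 3, 2), matrix(0, 3, 2))
  expect_equal(reconstruction_loss(H0, H0, c(1, 1)), 0)
  Hhat <- list(matrix(1:6, 3, 2) + 1, matrix(2, 3, 2))
  # gamma [1, 0] ignores modality 2 entirely
  expect_equal(reconstruction_loss(H0, Hhat, c(1, 0)), 6)
  # hand-set residuals: 6 entries off by 1 (m1), 6 entries off by 2 (m2)
  expect_equal(reconstruction_loss(H0, Hhat, c(1, 1)), 6 + 6 * 4)
  expect_equal(reconstruction_loss(H0, Hhat, c(2, 3)), 2 * 6 + 3 * 24)
  # correspondence loss is the same functional with its own weights
  expect_equal(correspondence_loss(H0, Hhat, c(5, 0)), 5 * 6)
  expect_equal(correspondence_loss(H0, H0, c(5, 7)), 0)
  # scaling gamma scales that modality's term linearly
  expect_equal(correspondence_loss(H0, Hhat, c(10, 1)),
               10 * 6 + 24)
  expect_error(reconstruction_loss(H0, list(matrix(0, 2, 2), H0[[2]]), 1),
               "shape")
})

test_that("analytic gradients match central finite differences", {
  for (L in 1:2) {
    toy <- make_toy_instance(n = 5, d_in = 3, d3 = 2, L = L, seed = 50 + L,
                             perturb = 0.1)
    gr <- c(1, 2); gc_ <- c(0.5, 3)
    fb <- spatialduet:::forward_backward(toy$H0, toy$A_s, toy$A_f,
                                         toy$state, gr, gc_)
    loss_at <- function(params) {
      st <- toy$state; st$params <- params
      spatialduet:::forward_backward(toy$H0, toy$A_s, toy$A_f, st, gr, gc_,
                                     want_grads = FALSE)$loss_total
    }
    h <- 1e-5
    for (k in names(toy$state$params)) {
      p <- toy$state$params[[k]]
      # probe a handful of entries per tensor to keep the test quick
      idx <- unique(round(seq(1, length(p), length.out = min(6, length(p)))))
      for (i in idx) {
        pp <- toy$state$params; pp[[k]][i] <- pp[[k]][i] + h
        pm <- toy$state$params; pm[[k]][i] <- pm[[k]][i] - h
        num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
        expect_equal(fb$grads[[k]][i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (L=%d)", k, i, L))
      }
    }
  }
})

test_that("training reduces the loss and the trace decomposes", {
  sim <- make_tiny_benchmark(seed = 52, grid = c(8, 8))
  cfg <- duet_config(epochs = 40, d_latent = 8, seed = 3, k_feature = 5)
  ds <- suppressWarnings(prepare_inputs(sim$dataset, cfg))
  tr <- train_model(ds, cfg)
  expect_lt(tr$trace$total[40], tr$trace$total[1])
  expect_true(all(tr$trace$recon >= 0 & tr$trace$corr >= 0))
  expect_equal(tr$trace$total, tr$trace$recon + tr$trace$corr,
               tolerance = 1e-6)
})

test_that("identical seeds reproduce the loss trace", {
  sim <- make_tiny_benchmark(seed = 53, grid = c(8, 8))
  cfg <- duet_config(epochs = 15, d_latent = 6, seed = 11, k_feature = 5)
  ds <- suppressWarnings(prepare_inputs(sim$dataset, cfg))
  t1 <- train_model(ds, cfg)
  t2 <- train_model(ds, cfg)
  expect_equal(t1$trace$total, t2$trace$total, tolerance = 1e-6)
  expect_identical(t1$forward$Z, t2$forward$Z)
})

test_that("duplicated modalities with tied initialisation keep beta at 1/2", {
  # same H0, same graphs, same initial parameters for both modalities: the
  # forward pass is symmetric at every training step, so the between-modality
  # weights must stay uniform throughout training
  sim <- make_tiny_benchmark(seed = 54, grid = c(7, 7))
  cfg <- duet_config(epochs = 25, d_latent = 6, seed = 5, k_feature = 5)
  ds <- suppressWarnings(prepare_inputs(sim$dataset, cfg))
  m1 <- ds$modalities[[1]]
  m2 <- m1; m2$name <- "copy"
  ds2 <- assemble_dataset(list(m1, m2), ds$coordinates)
  ds2$modalities[[1]]$processed <- m1$processed
  ds2$modalities[[2]]$processed <- m1$processed
  # tie the initial parameters of modality 2 to modality 1
  d_in <- ncol(m1$processed)
  tied_train <- local({
    A_s <- symmetric_normalize(build_spatial_graph(ds2$coordinates,
                                                   cfg$r_spatial))
    A_f <- symmetric_normalize(build_feature_graph(m1$processed,
                                                   cfg$k_feature))
    graphs <- list(A_s = A_s, A_f_list = list(A_f, A_f))
    state <- init_model_state(2, d_in, cfg)
    for (k in grep("_2_", names(state$params), value = TRUE))
      state$params[[k]] <- state$params[[sub("_2_", "_1_", k)]]
    state$params$Wq_2 <- state$params$Wq_1
    state$params$bq_2 <- state$params$bq_1
    state$params$q_2 <- state$params$q_1
    st <- list(m = lapply(state$params, function(x) x * 0),
               v = lapply(state$params, function(x) x * 0), t = 0L)
    H0 <- list(m1$processed, m1$processed)
    betas <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      fb <- spatialduet:::forward_backward(H0, graphs$A_s, graphs$A_f_list,
                                           state, 1, 1)
      betas[ep] <- max(abs(fb$beta - 0.5))
      upd <- spatialduet:::adam_step(state$params, fb$grads, st,
                                     cfg$learning_rate)
      state$params <- upd$params; st <- upd$st
    }
    betas
  })
  expect_lt(max(tied_train), 1e-9)
})

test_that("dataset presets return the published settings", {
  sp <- dataset_presets("spots_spleen")
  expect_equal(sp$gamma_recon, c(1, 5))
  expect_equal(sp$gamma_corr, c(1, 1))
  expect_equal(sp$epochs, 600L)
  expect_equal(sp$learning_rate, 1e-4)
  ly <- dataset_presets("visium_lymph")
  expect_equal(ly$gamma_recon, c(1, 5))
  expect_equal(ly$gamma_corr, c(10, 10))
  expect_equal(ly$epochs, 200L)
  th <- dataset_presets("stereo_cite_thymus")
  expect_equal(th$gamma_recon, c(1, 10))
  expect_equal(th$epochs, 1500L)
  br <- dataset_presets("spatial_epigenome_brain")
  expect_equal(br$gamma_recon, c(1, 5))
  expect_equal(br$epochs, 1600L)
  expect_error(dataset_presets("mystery"), "spots_spleen")
})

test_that("fit object methods expose the expected quantities", {
  sim <- make_tiny_benchmark(seed = 55, grid = c(8, 8))
  cfg <- duet_config(epochs = 10, d_latent = 6, seed = 7, k_feature = 5)
  fit <- suppressWarnings(duet(sim$dataset, cfg, n_clusters = 3))
  expect_s3_class(fit, "duet")
  expect_equal(dim(fit$Z), c(64L, 6L))
  expect_output(print(fit), "64 spots")
  s <- summary(fit)
  expect_s3_class(s, "summary.duet")
  expect_equal(rowSums(s$alpha_means), c(rna = 1, adt = 1), tolerance = 1e-6)
  expect_equal(predict(fit, "embedding"), fit$Z)
  res <- residuals(fit)
  expect_equal(res$rna,
               fit$dataset$modalities$rna$processed -
                 predict(fit, "reconstruction")$rna)
  expect_length(coef(fit), length(fit$state$params))
  expect_equal(sort(unique(fit$clusters)), 1:3)
})
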