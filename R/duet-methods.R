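#' @export
print.duet <- function(x, ...) {
  n <- nrow(x$Z)
  cat("Dual-attention spatial multi-omics integration fit\n")
  cat(sprintf("  %d spots, %d modalities (%s), latent dimension %d\n",
              n, ncol(x$beta), paste(colnames(x$beta), collapse = ", "),
              ncol(x$Z)))
  ep <- nrow(x$loss_trace)
  cat(sprintf("  %d epochs, final loss %.4f (recon %.4f + corr %.4f)\n",
              ep, x$loss_trace$total[ep], x$loss_trace$recon[ep],
              x$loss_trace$corr[ep]))
  if (!is.null(x$clusters))
    cat("  clusters:", length(unique(x$clusters)), "spatial domains\n")
  invisible(x)
}

#' Summarise a fitted integration model
#'
#' Reports the loss at start and end of training and the distribution of the
#' attention weights: per-modality mean within-modality weights (spatial vs
#' feature graph) and mean between-modality weights, which indicate how much
#' each graph and each modality contributed to the joint embedding.
#'
#' @param object A `duet` fit.
#' @param ... Unused.
#' @export
summary.duet <- function(object, ...) {
  ep <- nrow(object$loss_trace)
  out <- list(
    n_spots = nrow(object$Z),
    d_latent = ncol(object$Z),
    epochs = ep,
    loss_initial = object$loss_trace$total[1],
    loss_final = object$loss_trace$total[ep],
    alpha_means = t(vapply(object$alpha, colMeans, numeric(2))),
    beta_means = colMeans(object$beta),
    n_clusters = if (is.null(object$clusters)) NA_integer_
                 else length(unique(object$clusters)))
  class(out) <- "summary.duet"
  out
}

#' @export
print.summary.duet <- function(x, ...) {
  cat(sprintf("%d spots embedded in %d dimensions; loss %.4f -> %.4f over %d epochs\n",
              x$n_spots, x$d_latent, x$loss_initial, x$loss_final, x$epochs))
  cat("mean within-modality attention (rows = modalities):\n")
  print(round(x$alpha_means, 3))
  cat("mean between-modality attention:\n")
  print(round(x$beta_means, 3))
  invisible(x)
}

#' @export
coef.duet <- function(object, ...) object$state$params

#' Extract quantities from a fitted integration model
#'
#' @param object A `duet` fit.
#' @param type "embedding" (joint latent Z), "reconstruction" (per-modality
#'   reconstructed inputs), "alpha", or "beta".
#' @param ... Unused.
#' @export
predict.duet <- function(object,
                         type = c("embedding", "reconstruction", "alpha",
                                  "beta"), ...) {
  type <- match.arg(type)
  switch(type,
         embedding = object$Z,
         reconstruction = {
           r <- object$forward$H_hat
           names(r) <- colnames(object$beta)
           r
         },
         alpha = object$alpha,
         beta = object$beta)
}

#' @export
fitted.duet <- function(object, ...) object$Z

#' Per-modality reconstruction residuals
#'
#' @param object A `duet` fit.
#' @param ... Unused.
#' @return Named list of spot-by-d_in matrices `H0 - Hhat`.
#' @export
residuals.duet <- function(object, ...) {
  h0 <- lapply(object$dataset$modalities, `[[`, "processed")
  hh <- object$forward$H_hat
  r <- Map(`-`, h0, hh)
  names(r) <- colnames(object$beta)
  r
}

#' Plot a fitted integration model
#'
#' `which = "loss"` draws the training curves; `"domains"` a spatial scatter
#' of spots coloured by cluster (requires clusters); `"attention"` a spatial
#' scatter coloured by the first modality's between-modality weight.
#'
#' @param x A `duet` fit.
#' @param which "loss", "domains" or "attention".
#' @param ... Passed to the underlying plot call.
#' @export
plot.duet <- function(x, which = c("loss", "domains", "attention"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    tr <- x$loss_trace
    graphics::matplot(tr$epoch, tr[c("recon", "corr", "total")],
                      type = "l", lty = 1, col = c("steelblue", "tomato",
                                                   "black"),
                      xlab = "epoch", ylab = "loss", ...)
    graphics::legend("topright", c("recon", "corr", "total"), lty = 1,
                     col = c("steelblue", "tomato", "black"), bty = "n")
  } else {
    co <- x$dataset$coordinates
    if (which == "domains") {
      if (is.null(x$clusters)) stop("fit has no clusters; refit with ",
                                    "n_clusters or call cluster_latent()")
      graphics::plot(co[, 1], co[, 2], col = x$clusters + 1L, pch = 16,
                     cex = 0.6, xlab = "x", ylab = "y", asp = 1, ...)
    } else {
      w <- x$beta[, 1]
      pal <- grDevices::hcl.colors(100, "viridis")
      idx <- pmax(1L, ceiling(99 * (w - min(w)) /
                                max(1e-12, diff(range(w)))))
      graphics::plot(co[, 1], co[, 2], col = pal[idx], pch = 16, cex = 0.6,
                     xlab = "x", ylab = "y", asp = 1,
                     main = paste("attention weight:", colnames(x$beta)[1]),
                     ...)
    }
  }
  invisible(x)
}
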