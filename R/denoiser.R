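#' Train the gene-denoising autoencoder
#'
#' A symmetric seven-layer denoising autoencoder over the selected genes:
#' with `i` input genes the layer widths are
#' `[i, floor(0.5 i), floor(0.4 i), floor(0.3 i), floor(0.4 i),
#' floor(0.5 i), i]`.  Hidden units use ReLU activations, the output layer
#' is linear.  Each training epoch corrupts the (normalized) input with
#' fresh additive standard-normal noise and minimizes the mean squared
#' error between the raw input and the reconstruction, plus an L2 weight
#' penalty at scale `l2_scale`.  Optimization is full-batch AdaDelta.
#' Training stops after `patience` epochs without a reduction of the
#' minimum MSE, or at `max_epochs`; the weights at the minimum are kept.
#'
#' @param g_prime Data frame or matrix, patients x selected genes
#'   (normalized to `[0, 1]`); at least 2 patients and 4 genes.
#' @param patience Epochs without a new minimum MSE before stopping.
#' @param max_epochs Hard cap on training epochs.
#' @param l2_scale L2 penalty coefficient.
#' @param noise_sd Sd of the additive corruption noise.
#' @param rho,eps AdaDelta decay rate and stabilizer.
#' @param seed Integer seed (initialization and noise draws).
#' @return A `mult_denoiser` model with elements `widths`, `weights`,
#'   `biases`, `trace` (per-epoch reconstruction MSE) and `best_mse`.
#' @export
train_denoiser <- function(g_prime, patience = 1000, max_epochs = 5000,
                           l2_scale = 0.01, noise_sd = 1, rho = 0.95,
                           eps = 1e-6, seed = 1) {
  x <- df_to_matrix(g_prime)
  n <- nrow(x)
  i <- ncol(x)
  if (n < 2) abort("need at least 2 training patients")
  if (i < 4) abort("need at least 4 selected genes (hidden widths >= 1)")
  widths <- c(i, floor(0.5 * i), floor(0.4 * i), floor(0.3 * i),
              floor(0.4 * i), floor(0.5 * i), i)
  nl <- length(widths) - 1L

  with_seed(seed, {
    W <- map(seq_len(nl), function(l) {
      matrix(rnorm(widths[l] * widths[l + 1], sd = sqrt(2 / widths[l])),
             widths[l], widths[l + 1])
    })
    b <- map(seq_len(nl), function(l) numeric(widths[l + 1]))
    EgW <- map(W, function(w) w * 0); EdW <- EgW
    Egb <- map(b, function(v) v * 0); Edb <- Egb

    best_mse <- Inf
    best_W <- W; best_b <- b
    stall <- 0
    trace <- numeric(0)

    for (epoch in seq_len(max_epochs)) {
      xn <- x + matrix(rnorm(n * i, sd = noise_sd), n, i)
      ## forward
      a <- vector("list", nl + 1)
      z <- vector("list", nl)
      a[[1]] <- xn
      for (l in seq_len(nl)) {
        z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < nl) pmax(z[[l]], 0) else z[[l]]
      }
      out <- a[[nl + 1]]
      mse <- mean((out - x)^2)
      if (!is.finite(mse)) {
        abort("non-finite denoiser training loss",
              class = "multsens_denoiser_error", trace = trace)
      }
      trace <- c(trace, mse)
      if (mse < best_mse) {
        best_mse <- mse
        best_W <- W; best_b <- b
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
      ## backward
      delta <- 2 * (out - x) / (n * i)
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(a[[l]], delta) + 2 * l2_scale * W[[l]]
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (z[[l - 1]] > 0)
        EgW[[l]] <- rho * EgW[[l]] + (1 - rho) * gW^2
        stepW <- -sqrt(EdW[[l]] + eps) / sqrt(EgW[[l]] + eps) * gW
        EdW[[l]] <- rho * EdW[[l]] + (1 - rho) * stepW^2
        W[[l]] <- W[[l]] + stepW
        Egb[[l]] <- rho * Egb[[l]] + (1 - rho) * gb^2
        stepb <- -sqrt(Edb[[l]] + eps) / sqrt(Egb[[l]] + eps) * gb
        Edb[[l]] <- rho * Edb[[l]] + (1 - rho) * stepb^2
        b[[l]] <- b[[l]] + stepb
      }
    }
  })
  structure(
    list(widths = widths, weights = best_W, biases = best_b,
         genes = colnames(x), trace = trace, best_mse = best_mse,
         noise_sd = noise_sd, l2_scale = l2_scale),
    class = "mult_denoiser")
}

#' @export
print.mult_denoiser <- function(x, ...) {
  cat("<mult_denoiser> widths [", paste(x$widths, collapse = ", "),
      "], best MSE ", signif(x$best_mse, 4), " after ",
      length(x$trace), " epochs\n", sep = "")
  invisible(x)
}

#' Denoise gene-expression rows with a trained autoencoder
#'
#' Deterministic forward pass on clean (un-noised) inputs using the
#' weights checkpointed at the minimum training MSE.
#'
#' @param model A [train_denoiser()] model.
#' @param g_prime Patients x genes table over the training gene set.
#' @return Matrix of denoised expression, same shape as the input.
#' @export
denoise <- function(model, g_prime) {
  m <- df_to_matrix(g_prime)
  if (!identical(colnames(m), model$genes)) {
    abort("gene set does not match the denoiser training gene set")
  }
  nl <- length(model$weights)
  a <- m
  for (l in seq_len(nl)) {
    zz <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    a <- if (l < nl) pmax(zz, 0) else zz
  }
  colnames(a) <- paste0("Gd_", model$genes)
  rownames(a) <- rownames(m)
  a
}
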