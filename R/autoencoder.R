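#' Train a stacked autoencoder on attribute vectors
#'
#' Greedy layer-wise training: each layer is an autoencoder
#' `h = relu(W x + p)`, `y = relu(W' h + q)` fitted by minimizing mean
#' squared reconstruction error on the previous layer's codes; the encoder
#' stack maps raw attribute vectors (non-negative frequencies or
#' similarities) to the final hidden dimension. ReLU is used on both the
#' encoder and the decoder, matching the non-negative input range.
#' Optimization is mini-batch Adam; all randomness (init, batch order) flows
#' from `seed`, so training is deterministic.
#'
#' @param data Numeric matrix, one attribute vector per row; all finite.
#' @param hidden_sizes Integer vector of hidden layer widths; the last entry
#'   is the output code dimension (default 64).
#' @param epochs Training epochs per layer.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param batch_size Mini-batch size.
#' @return Object of class `sae`: list of per-layer parameter lists
#'   (`W`, `p`, `Wd`, `q`) plus a `loss` data.frame with the initial and
#'   final full-data MSE of every layer.
#' @export
sae_train <- function(data, hidden_sizes = 64, epochs = 100, lr = 2e-3,
                      seed = 1, batch_size = 32) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("non-finite values in training data", call. = FALSE)
  if (nrow(data) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (any(hidden_sizes > ncol(data))) {
    warning("hidden size exceeds input size; layer is over-complete",
            call. = FALSE)
  }
  set.seed(seed)
  layers <- vector("list", length(hidden_sizes))
  loss <- data.frame(layer = integer(0), initial = numeric(0),
                     final = numeric(0))
  H <- data
  for (li in seq_along(hidden_sizes)) {
    fit <- .ae_fit_layer(H, hidden_sizes[li], epochs, lr, batch_size)
    layers[[li]] <- fit$par
    loss <- rbind(loss, data.frame(layer = li, initial = fit$initial,
                                   final = fit$final))
    H <- .relu(H %*% t(fit$par$W) + rep(fit$par$p, each = nrow(H)))
  }
  structure(list(layers = layers, loss = loss,
                 input_dim = ncol(data), code_dim = utils::tail(hidden_sizes, 1)),
            class = "sae")
}

.relu <- function(x) pmax(x, 0)

.ae_fit_layer <- function(X, h, epochs, lr, batch_size) {
  n <- nrow(X); p <- ncol(X)
  # PCA initialization: start at the optimal linear autoencoder with every
  # ReLU in its active regime (randomly initialized ReLU autoencoders of
  # this width reliably stall in poor local minima); the hidden offset c0
  # keeps codes positive and the decoder bias undoes it. Small Gaussian
  # noise breaks symmetry so gradient refinement can improve on the
  # linear optimum.
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(h, p, n))
  V <- sv$v
  if (ncol(V) < h) V <- cbind(V, matrix(0, p, h - ncol(V)))
  scores <- Xc %*% V
  c0 <- pmax(-apply(scores, 2, min), 0) + 0.1
  W  <- t(V) + matrix(stats::rnorm(h * p, sd = 0.01), h, p)
  bp <- as.numeric(c0 - t(V) %*% mu) + stats::rnorm(h, sd = 0.01)
  Wd <- V + matrix(stats::rnorm(p * h, sd = 0.01), p, h)
  bq <- as.numeric(mu - V %*% c0) + stats::rnorm(p, sd = 0.01)
  pars <- list(W = W, p = bp, Wd = Wd, q = bq)
  # Adam state
  m <- lapply(pars, function(z) z * 0); v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  full_mse <- function(pr) {
    Hh <- .relu(X %*% t(pr$W) + rep(pr$p, each = n))
    Y  <- .relu(Hh %*% t(pr$Wd) + rep(pr$q, each = n))
    mean((Y - X)^2)
  }
  initial <- full_mse(pars)
  best <- Inf; best_pars <- pars

  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1, n)]
      Xb <- X[b, , drop = FALSE]; nb <- length(b)
      Zh <- Xb %*% t(pars$W) + rep(pars$p, each = nb)
      Hh <- .relu(Zh)
      Zy <- Hh %*% t(pars$Wd) + rep(pars$q, each = nb)
      Y  <- .relu(Zy)
      dY <- 2 * (Y - Xb) / (nb * p)
      dZy <- dY * (Zy > 0)
      gWd <- t(dZy) %*% Hh
      gq  <- colSums(dZy)
      dH  <- dZy %*% pars$Wd
      dZh <- dH * (Zh > 0)
      gW  <- t(dZh) %*% Xb
      gp  <- colSums(dZh)
      g <- list(W = gW, p = gp, Wd = gWd, q = gq)
      t <- t + 1
      for (nm in names(pars)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^t)
        vhat <- v[[nm]] / (1 - b2^t)
        pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    # keep the best end-of-epoch parameters: refinement from the PCA start
    # must never return a worse model than an earlier epoch produced
    cur <- full_mse(pars)
    if (cur < best) { best <- cur; best_pars <- pars }
  }
  list(par = best_pars, initial = initial, final = best)
}

#' Encode attribute vectors through a trained stacked autoencoder
#' @param model A fitted `sae`.
#' @param x Numeric vector or matrix (rows = samples) with the model's input
#'   dimension.
#' @return Matrix of codes (rows = samples, `model$code_dim` columns).
#' @export
sae_encode <- function(model, x) {
  stopifnot(inherits(model, "sae"))
  H <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(H) != model$input_dim) {
    stop("input has ", ncol(H), " columns; model expects ", model$input_dim,
         call. = FALSE)
  }
  rn <- rownames(H)
  for (ly in model$layers) {
    H <- .relu(H %*% t(ly$W) + rep(ly$p, each = nrow(H)))
  }
  rownames(H) <- rn
  H
}

#' Decode hidden codes back to the input space
#' @param model A fitted `sae`.
#' @param h Numeric vector or matrix of codes (`model$code_dim` columns).
#' @return Matrix of reconstructions in the input dimension.
#' @export
sae_decode <- function(model, h) {
  stopifnot(inherits(model, "sae"))
  Y <- if (is.null(dim(h))) matrix(h, nrow = 1) else as.matrix(h)
  if (ncol(Y) != model$code_dim) {
    stop("codes have ", ncol(Y), " columns; model expects ", model$code_dim,
         call. = FALSE)
  }
  for (ly in rev(model$layers)) {
    Y <- .relu(Y %*% t(ly$Wd) + rep(ly$q, each = nrow(Y)))
  }
  Y
}
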