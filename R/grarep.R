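#' Random-walk transition matrix of an adjacency matrix
#'
#' `A = D^-1 S` where `D` is the degree diagonal: each non-isolated row of
#' the symmetric binary adjacency `S` is divided by its degree, so rows sum
#' to 1. Isolated nodes keep an all-zero row and are flagged with a warning.
#'
#' @param S Square symmetric binary adjacency (base or `Matrix`), zero
#'   diagonal.
#' @return Dense numeric row-stochastic matrix.
#' @export
transition_matrix <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("adjacency must be square", call. = FALSE)
  deg <- rowSums(S)
  isolated <- deg == 0
  if (any(isolated)) {
    warning(sum(isolated), " isolated node(s): zero transition row(s)",
            call. = FALSE)
    deg[isolated] <- 1  # avoid 0/0; row stays all-zero
  }
  A <- S / deg
  dimnames(A) <- dimnames(S)
  A
}

#' k-step transition matrix
#' @param A Row-stochastic transition matrix.
#' @param k Step order, integer >= 1.
#' @return `A` raised to the `k`-th power (matrix product).
#' @export
k_step_matrix <- function(A, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  Ak <- A
  if (k > 1) for (i in seq_len(k - 1)) Ak <- Ak %*% A
  Ak
}

#' Shifted log-probability matrix of a k-step transition matrix
#'
#' Each column is first normalized by its sum `Gamma_j` (the common-neighbor
#' normalizer), then `X_ij = log(Ak_ij / Gamma_j) - log(beta)`; entries where
#' `Ak_ij = 0`, or where the shifted log is negative, are truncated to 0.
#' Natural logarithm throughout. The default shift is `beta = 1/N`.
#'
#' @param Ak k-step transition matrix.
#' @param beta Positive shift constant; default `1/nrow(Ak)`.
#' @return Non-negative matrix of the same shape.
#' @export
log_probability_matrix <- function(Ak, beta = 1 / nrow(Ak)) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a positive scalar", call. = FALSE)
  }
  gamma <- colSums(Ak)
  gamma[gamma == 0] <- 1  # columns never reached; entries are all 0 anyway
  X <- log(sweep(Ak, 2, gamma, "/")) - log(beta)
  X[Ak == 0] <- 0
  X[X < 0] <- 0
  X
}

.sign_fix <- function(U) {
  # deterministic sign convention: largest-|entry| of each column positive
  for (c in seq_len(ncol(U))) {
    m <- which.max(abs(U[, c]))
    if (U[m, c] < 0) U[, c] <- -U[, c]
  }
  U
}

#' Rank-d factorization of a log-probability matrix
#'
#' Truncated SVD `X = U S V'`; the per-order node representation is
#' `W = U_d sqrt(S_d)`. A fixed sign convention (largest-magnitude entry of
#' each left singular vector made positive) makes the output deterministic.
#' Uses LAPACK dense SVD, which is exact and bit-reproducible at the network
#' sizes in scope.
#'
#' @param X Non-negative log-probability matrix.
#' @param d Embedding dimension, `1 <= d <= nrow(X)`.
#' @return List with `W` (N x d), `d_values` (top-d singular values), and
#'   `U`, `V` (sign-fixed truncated factors).
#' @export
factorize <- function(X, d) {
  n <- nrow(X)
  if (!is.numeric(d) || length(d) != 1 || d < 1 || d != round(d)) {
    stop("d must be a positive integer", call. = FALSE)
  }
  if (d > n) stop("d = ", d, " exceeds matrix size ", n, call. = FALSE)
  sv <- svd(X, nu = d, nv = d)
  U <- sv$u; V <- sv$v
  # align V's signs with U before fixing so U S V' still reconstructs X
  for (c in seq_len(d)) {
    m <- which.max(abs(U[, c]))
    if (U[m, c] < 0) { U[, c] <- -U[, c]; V[, c] <- -V[, c] }
  }
  s <- sv$d[seq_len(d)]
  W <- U * rep(sqrt(s), each = n)
  rownames(W) <- rownames(X)
  list(W = W, d_values = s, U = U, V = V)
}

#' GraRep node embedding of a network adjacency matrix
#'
#' For each step order `k = 1..K`: form the k-step transition matrix, its
#' shifted log-probability matrix, and its rank-`d` SVD factor; the final
#' embedding concatenates the per-order factors column-wise, giving each
#' node a `K*d`-dimensional behavior vector capturing multi-step
#' neighborhood structure.
#'
#' @param S Adjacency matrix (symmetric binary, zero diagonal).
#' @param K Maximum step order (default 4).
#' @param d Dimensions per order (default 16, so `K*d = 64`).
#' @param beta Log-shift constant; default `1/N`.
#' @return Numeric matrix `N x (K*d)`, rows in adjacency (node) order, with
#'   attributes `K`, `d`.
#' @export
grarep_embed <- function(S, K = 4, d = 16, beta = 1 / nrow(S)) {
  if (!is.numeric(K) || K < 1 || K != round(K)) {
    stop("K must be an integer >= 1", call. = FALSE)
  }
  A <- transition_matrix(S)
  blocks <- vector("list", K)
  Ak <- A
  for (k in seq_len(K)) {
    if (k > 1) Ak <- Ak %*% A
    X <- log_probability_matrix(Ak, beta)
    blocks[[k]] <- factorize(X, d)$W
  }
  W <- do.call(cbind, blocks)
  colnames(W) <- paste0("k", rep(seq_len(K), each = d), "_", seq_len(d))
  rownames(W) <- rownames(as.matrix(S))
  attr(W, "K") <- K
  attr(W, "d") <- d
  W
}
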