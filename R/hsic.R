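## Hilbert-Schmidt independence criterion: biased V-statistic estimator
## trace(K H L H) / (n-1)^2 with Gaussian kernels and median-heuristic
## bandwidths, plus its gradient with respect to the samples (needed to push
## newly added latent nodes towards independence from existing ones).

# squared pairwise distance matrix of a single variable
.sqdist1 <- function(x) {
  d <- outer(x, x, "-")
  d * d
}

# median-heuristic squared bandwidth from a squared-distance matrix;
# falls back to 1 for (near-)constant samples
.med_bw2 <- function(D2) {
  off <- D2[upper.tri(D2)]
  m <- stats::median(off)
  if (!is.finite(m) || m <= 0) 1 else m
}

# Gaussian product kernel over the columns of Y with per-column
# median-heuristic bandwidths; returns the Gram matrix and the bandwidths
.gram <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  S <- matrix(0, n, n)
  bw2 <- numeric(ncol(Y))
  for (d in seq_len(ncol(Y))) {
    D2 <- .sqdist1(Y[, d])
    bw2[d] <- .med_bw2(D2)
    S <- S + D2 / bw2[d]
  }
  list(K = exp(-S / 2), bw2 = bw2)
}

#' Sample estimate of the Hilbert-Schmidt independence criterion
#'
#' Biased V-statistic estimator `trace(K H L H) / (n - 1)^2`, where `K` and
#' `L` are Gaussian Gram matrices of `x` and `Y` and `H = I - 1/n` is the
#' centering matrix. Bandwidths follow the median heuristic, applied per
#' variable (columns of `Y` enter through a product kernel). The estimate is
#' nonnegative up to numerical round-off, zero for constant input, and small
#' for independent samples.
#'
#' @param x Numeric vector of `n` samples of the first variable.
#' @param Y Numeric vector or `n x d` matrix of samples of the second
#'   variable (set).
#' @return Nonnegative scalar dependence estimate.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' hsic(x, rnorm(100))   # independent: near 0
#' hsic(x, cbind(x^2))   # dependent: elevated
#' @export
hsic <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- length(x)
  if (n < 4L) stop("hsic requires at least 4 samples (centering is degenerate)")
  if (nrow(Y) != n) stop("x and Y must have the same number of samples")
  K <- exp(-.sqdist1(x) / (2 * .med_bw2(.sqdist1(x))))
  L <- .gram(Y)$K
  Kc <- K - rowMeans(K)                       # H K
  Kc <- Kc - rep(colMeans(Kc), each = n)      # H K H
  sum(Kc * L) / (n - 1)^2
}

# double centering: H M H with H = I - 1/n, computed by row/column means
.center2 <- function(M) {
  M <- M - rowMeans(M)
  M - rep(colMeans(M), each = nrow(M))
}

# Shared machinery for the summed penalty over new nodes: the per-column
# signed difference matrices, bandwidths and scaled squared distances are
# computed once and reused by every node term (each node's "other variables"
# Gram matrix is the full product kernel divided by the node's own factor).
.hsic_terms <- function(Z, new_idx, grad = FALSE) {
  n <- nrow(Z)
  P <- ncol(Z)
  if (length(new_idx) == 0L || n < 4L) {
    return(list(value = 0, grad = matrix(0, n, P)))
  }
  Dsign <- vector("list", P)
  A <- vector("list", P)          # squared distances / bandwidth
  bw2 <- numeric(P)
  Tsum <- matrix(0, n, n)
  for (j in seq_len(P)) {
    Dsign[[j]] <- outer(Z[, j], Z[, j], "-")
    D2 <- Dsign[[j]]^2
    bw2[j] <- .med_bw2(D2)
    A[[j]] <- D2 / bw2[j]
    Tsum <- Tsum + A[[j]]
  }
  sc <- 1 / (n - 1)^2
  val <- 0
  G <- matrix(0, n, P)
  for (k in new_idx) {
    K <- exp(-A[[k]] / 2)
    L <- exp(-(Tsum - A[[k]]) / 2)
    HLH <- .center2(L)
    val <- val + sum(.center2(K) * L) * sc
    if (grad) {
      # d/dK trace(KHLH) = HLH ; dK_ij/dx_i = -K_ij (x_i - x_j) / bw2_k
      G[, k] <- G[, k] - 2 * sc * rowSums(HLH * K * Dsign[[k]]) / bw2[k]
      # d/dL trace(KHLH) = HKH ; dL_ij/dy_ij^(j') analogous per column
      W <- .center2(K) * L
      for (j in seq_len(P)[-k]) {
        G[, j] <- G[, j] - 2 * sc * rowSums(W * Dsign[[j]]) / bw2[j]
      }
    }
  }
  list(value = val, grad = G)
}

# hsic summed over each column in new_idx of Z versus all other columns
hsic_total <- function(Z, new_idx) {
  .hsic_terms(Z, new_idx, grad = FALSE)$value
}

# gradient of hsic_total with respect to Z (bandwidths treated as constants)
hsic_total_grad <- function(Z, new_idx) {
  .hsic_terms(Z, new_idx, grad = TRUE)$grad
}
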