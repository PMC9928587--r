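## Amortized Gaussian encoder: a small fully connected network mapping
## log1p-transformed counts concatenated with the condition one-hot to the
## per-cell posterior mean and variance. Variances go through a softplus so
## they are strictly positive. Written directly on BLAS matrix products with
## hand-derived backpropagation; no framework is involved.

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style initialization; draws from the current RNG stream
init_encoder <- function(n_in, hidden, n_latent) {
  stopifnot(length(hidden) >= 1L)
  dims <- c(n_in, hidden)
  W <- list(); b <- list()
  for (l in seq_along(hidden)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  h_out <- hidden[length(hidden)]
  list(
    W = W, b = b,
    Wmu = matrix(stats::rnorm(h_out * n_latent, sd = sqrt(1 / h_out)), h_out, n_latent),
    bmu = rep(0, n_latent),
    Ws = matrix(stats::rnorm(h_out * n_latent, sd = sqrt(1 / h_out)), h_out, n_latent),
    bs = rep(0, n_latent)
  )
}

# forward pass; U is the (batch x n_in) input. Returns posterior parameters
# and the activation cache needed for backpropagation.
encoder_forward <- function(enc, U) {
  A <- list(U)
  h <- U
  for (l in seq_along(enc$W)) {
    h <- h %*% enc$W[[l]]
    h <- sweep(h, 2L, enc$b[[l]], "+")
    h[h < 0] <- 0                      # ReLU
    A[[l + 1L]] <- h
  }
  mu <- sweep(h %*% enc$Wmu, 2L, enc$bmu, "+")
  sraw <- sweep(h %*% enc$Ws, 2L, enc$bs, "+")
  list(mu = mu, sigma2 = .softplus(sraw), sraw = sraw, A = A)
}

# backward pass: gradients of the loss with respect to all encoder tensors,
# given gradients with respect to mu and sigma2
encoder_backward <- function(enc, fwd, dmu, dsigma2) {
  dsraw <- dsigma2 * .sigmoid(fwd$sraw)
  h <- fwd$A[[length(fwd$A)]]
  g <- list(
    Wmu = crossprod(h, dmu), bmu = colSums(dmu),
    Ws = crossprod(h, dsraw), bs = colSums(dsraw),
    W = vector("list", length(enc$W)), b = vector("list", length(enc$W))
  )
  dh <- dmu %*% t(enc$Wmu) + dsraw %*% t(enc$Ws)
  for (l in rev(seq_along(enc$W))) {
    dh[fwd$A[[l + 1L]] <= 0] <- 0      # through ReLU
    g$W[[l]] <- crossprod(fwd$A[[l]], dh)
    g$b[[l]] <- colSums(dh)
    if (l > 1L) dh <- dh %*% t(enc$W[[l]])
  }
  g
}

## Adam optimizer state handled as flat lists of tensors keyed by name.

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
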