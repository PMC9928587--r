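# Independent numerical oracles used across the suite.

# Numerical proximal operator: minimizes 0.5||l - v||^2 + penalty(l) by
# quasi-Newton descent on a smoothed penalty (|x| ~ sqrt(x^2 + eps)), started
# from both v and 0, keeping the better optimum. Smoothing eps is tiny enough
# that the minimizer agrees with the exact prox to well below 1e-6.
numerical_prox <- function(v, alpha2 = 0, gamma1 = 0, m = rep(1, length(v)),
                           eps = 1e-18) {
  obj <- function(l) {
    0.5 * sum((l - v)^2) + alpha2 * sqrt(sum(l^2) + eps) +
      gamma1 * sum(m * sqrt(l^2 + eps))
  }
  grd <- function(l) {
    (l - v) + alpha2 * l / sqrt(sum(l^2) + eps) +
      gamma1 * m * l / sqrt(l^2 + eps)
  }
  best <- NULL
  for (start in list(v, rep(0, length(v)))) {
    o <- stats::optim(start, obj, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish with damped Newton steps until the gradient vanishes; function
  # value differences hit machine noise long before the argmin does
  l <- best$par
  d <- length(v)
  for (it in 1:100) {
    g <- grd(l)
    if (max(abs(g)) < 1e-11) break
    s2 <- sum(l^2) + eps
    Hm <- diag(1 + gamma1 * m * eps / (l^2 + eps)^1.5, d) +
      alpha2 * (diag(d) / sqrt(s2) - tcrossprod(l) / s2^1.5)
    step <- tryCatch(solve(Hm, g), error = function(e) g)
    ok <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      cand <- l - damp * step
      if (obj(cand) <= obj(l)) { l <- cand; ok <- TRUE; break }
    }
    if (!ok) break
  }
  l
}

# Brute-force HSIC: unvectorized double loops over the Gram matrices with the
# same median-heuristic bandwidths, computing trace(K H L H) / (n-1)^2.
hsic_bruteforce <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- length(x)
  med_bw2 <- function(z) {
    d2 <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) d2 <- c(d2, (z[i] - z[j])^2)
    m <- stats::median(d2)
    if (!is.finite(m) || m <= 0) 1 else m
  }
  K <- matrix(0, n, n)
  bx <- med_bw2(x)
  for (i in 1:n) for (j in 1:n) K[i, j] <- exp(-(x[i] - x[j])^2 / (2 * bx))
  L <- matrix(1, n, n)
  for (d in seq_len(ncol(Y))) {
    bd <- med_bw2(Y[, d])
    for (i in 1:n) for (j in 1:n) {
      L[i, j] <- L[i, j] * exp(-(Y[i, d] - Y[j, d])^2 / (2 * bd))
    }
  }
  H <- diag(n) - matrix(1 / n, n, n)
  sum(diag(K %*% H %*% L %*% H)) / (n - 1)^2
}

# Direct log-gamma evaluation of the NB log-pmf in mean/dispersion form.
nb_logpmf_direct <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) + x * (log(mu) - log(theta + mu))
}

# area under the ROC curve via the rank-sum statistic
auc_score <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
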