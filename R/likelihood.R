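#' Negative-binomial log-likelihood per cell
#'
#' Log-probability mass of counts under the mean/dispersion parameterization
#' of the negative binomial (mean `mu`, dispersion `theta`; variance
#' `mu + mu^2 / theta`), summed over genes within each cell.
#'
#' @param x Nonnegative integer count matrix (cells x genes) or vector.
#' @param mu Positive mean matrix/vector, same shape as `x` (recycled if
#'   scalar).
#' @param theta Positive dispersion matrix/vector, same shape as `x`
#'   (recycled if scalar).
#' @return Numeric vector with one log-likelihood per cell (per row), or a
#'   scalar for vector input.
#' @examples
#' nb_loglik(c(0, 3), mu = 2, theta = 5)
#' @export
nb_loglik <- function(x, mu, theta) {
  if (any(x < 0)) stop("counts must be nonnegative")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("counts must be integers; the negative-binomial likelihood requires raw counts")
  }
  stopifnot(all(mu > 0), all(theta > 0))
  ll <- stats::dnbinom(as.vector(round(x)), size = as.vector(theta + 0 * x),
                       mu = as.vector(mu + 0 * x), log = TRUE)
  if (is.matrix(x)) rowSums(matrix(ll, nrow = nrow(x))) else sum(ll)
}

#' KL divergence of diagonal-Gaussian posteriors from the standard normal
#'
#' Closed-form `KL(N(mu, diag(sigma2)) || N(0, I))`, summed over latent
#' dimensions for each cell.
#'
#' @param mu Matrix of posterior means (cells x latent dims) or vector.
#' @param sigma2 Matrix/vector of posterior variances, strictly positive.
#' @return Numeric vector with one KL value per cell.
#' @examples
#' kl_gaussian(matrix(0, 2, 3), matrix(1, 2, 3))  # zero
#' @export
kl_gaussian <- function(mu, sigma2) {
  stopifnot(all(sigma2 > 0))
  term <- 0.5 * (mu^2 + sigma2 - log(sigma2) - 1)
  if (is.matrix(term)) rowSums(term) else sum(term)
}
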