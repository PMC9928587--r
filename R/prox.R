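#' Proximal operators for structured decoder sparsity
#'
#' Closed-form proximal operators used after each stochastic gradient step on
#' the decoder weight matrix. `prox_l1()` is elementwise soft thresholding,
#' the proximal map of `t * ||.||_1`; `prox_group_lasso()` is block soft
#' thresholding, the proximal map of `t * ||.||_2`, which returns an exactly
#' zero vector when `||v||_2 <= t` (this is what deactivates whole gene
#' programs); `prox_masked_l1()` soft-thresholds only the entries flagged by a
#' binary mask (the non-members of a program), leaving annotated members
#' untouched; `prox_gp_column()` composes the two — masked soft thresholding
#' followed by group shrinkage — which is the exact proximal map of the summed
#' penalty `eta_alpha * ||.||_2 + eta_gamma * ||. * m||_1`.
#'
#' @param v Numeric vector (one decoder column).
#' @param t Nonnegative threshold (penalty strength times learning rate).
#' @param m Binary vector, same length as `v`; 1 marks penalized entries.
#' @param eta_alpha Nonnegative group-lasso threshold.
#' @param eta_gamma Nonnegative masked-L1 threshold.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' prox_l1(c(2, -2, 0.3), 0.5)
#' prox_group_lasso(c(3, 4), 1)
#' prox_gp_column(c(3, 4), c(0, 1), 1, 0.5)
#' @name prox
NULL

#' @rdname prox
#' @export
prox_l1 <- function(v, t) {
  stopifnot(t >= 0)
  sign(v) * pmax(abs(v) - t, 0)
}

#' @rdname prox
#' @export
prox_group_lasso <- function(v, t) {
  stopifnot(t >= 0)
  nrm <- sqrt(sum(v^2))
  if (nrm > t) v * (1 - t / nrm) else rep(0, length(v))
}

#' @rdname prox
#' @export
prox_masked_l1 <- function(v, m, t) {
  if (length(m) != length(v)) stop("mask length must equal vector length")
  stopifnot(t >= 0)
  out <- v
  pen <- m != 0
  out[pen] <- sign(v[pen]) * pmax(abs(v[pen]) - t, 0)
  out
}

#' @rdname prox
#' @export
prox_gp_column <- function(v, m, eta_alpha, eta_gamma) {
  prox_group_lasso(prox_masked_l1(v, m, eta_gamma), eta_alpha)
}

#' Proximal configuration
#'
#' Bundles the penalty strengths entering the proximal update of the decoder
#' weights. `alpha` is the group-lasso strength that can switch whole curated
#' programs off; `gamma` is the soft-membership L1 strength applied through
#' the mask complement on curated soft columns (and to every entry of
#' reference-time unconstrained sparse columns); `gamma_ext` is the plain L1
#' strength on new unconstrained columns added at query time; `alpha_l1` is
#' the masked-L1 strength on new constrained soft columns. Each threshold is
#' multiplied by the decoder learning rate `eta` at application time.
#'
#' @param alpha Group-lasso strength (default 0.7, suitable for up to a few
#'   hundred programs; increase for larger collections).
#' @param gamma Soft-membership L1 strength (default 0.7).
#' @param gamma_ext L1 strength for new unconstrained columns (default 0.1).
#'   Unlike `alpha`, which thresholds a whole column norm, `gamma_ext` acts
#'   per entry, so useful values are a few times `alpha / sqrt(n_genes)`;
#'   stronger values consolidate redundant new nodes.
#' @param alpha_l1 Masked-L1 strength for new constrained soft columns
#'   (default 0.7).
#' @param group_lasso_hard Apply group lasso to hard-membership columns as
#'   well as soft ones (default `TRUE`).
#' @return A list of class `prox_config`.
#' @export
prox_config <- function(alpha = 0.7, gamma = 0.7, gamma_ext = 0.1,
                        alpha_l1 = 0.7, group_lasso_hard = TRUE) {
  stopifnot(alpha >= 0, gamma >= 0, gamma_ext >= 0, alpha_l1 >= 0)
  structure(list(alpha = alpha, gamma = gamma, gamma_ext = gamma_ext,
                 alpha_l1 = alpha_l1, group_lasso_hard = group_lasso_hard),
            class = "prox_config")
}

#' Apply the per-column proximal update to a decoder weight matrix
#'
#' The joint penalty is separable in columns, so the full proximal map is the
#' per-column application of the operator matching each column's role:
#' \describe{
#'   \item{hard}{non-member entries zeroed (mask enforcement), then group-lasso
#'     shrinkage with threshold `eta * alpha`;}
#'   \item{soft}{masked soft threshold `eta * gamma` on non-members, then
#'     group-lasso shrinkage `eta * alpha` (for an all-ones mask column this is
#'     plain L1 followed by group lasso);}
#'   \item{new_unconstrained}{plain soft threshold `eta * gamma_ext`, no group
#'     lasso;}
#'   \item{new_constrained_soft}{masked soft threshold `eta * alpha_l1`;}
#'   \item{new_constrained_hard}{non-member entries zeroed.}
#' }
#' Columns listed in `frozen_cols` are returned untouched.
#'
#' @param W Decoder weight matrix, genes x programs.
#' @param M Binary penalty mask of the same shape (complement of membership).
#' @param roles Character vector, one role per column.
#' @param eta Nonnegative decoder learning rate entering every threshold.
#' @param cfg A [prox_config()].
#' @param frozen_cols Optional integer/logical index of columns to skip.
#' @return Updated matrix of the same shape.
#' @export
apply_decoder_prox <- function(W, M, roles, eta, cfg, frozen_cols = NULL) {
  stopifnot(ncol(W) == length(roles), all(dim(W) == dim(M)), eta >= 0)
  frozen <- rep(FALSE, ncol(W))
  if (!is.null(frozen_cols)) frozen[frozen_cols] <- TRUE
  for (j in seq_len(ncol(W))) {
    if (frozen[j]) next
    v <- W[, j]
    m <- M[, j]
    W[, j] <- switch(roles[j],
      hard = {
        v[m != 0] <- 0
        if (cfg$group_lasso_hard) prox_group_lasso(v, eta * cfg$alpha) else v
      },
      soft = prox_gp_column(v, m, eta * cfg$alpha, eta * cfg$gamma),
      new_unconstrained = prox_l1(v, eta * cfg$gamma_ext),
      new_constrained_soft = prox_masked_l1(v, m, eta * cfg$alpha_l1),
      new_constrained_hard = {
        v[m != 0] <- 0
        v
      },
      stop("unknown column role '", roles[j], "'")
    )
  }
  W
}

#' Soft-membership penalty value
#'
#' Reports `gamma * sum_j ||W[,j] * M[,j]||_1`, the L1 penalty on decoder
#' weights outside their programs' annotation. The penalty is enforced through
#' the proximal step, not by differentiation; this function exists for
#' monitoring.
#'
#' @param W Decoder weight matrix.
#' @param M Binary penalty mask of the same shape.
#' @param gamma Nonnegative penalty strength.
#' @return Nonnegative scalar.
#' @export
soft_mask_penalty <- function(W, M, gamma) {
  stopifnot(all(dim(W) == dim(M)), gamma >= 0)
  gamma * sum(abs(W * M))
}
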