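#' Fit a gene-program conditional variational autoencoder
#'
#' Trains a conditional VAE on raw single-cell counts in which every latent
#' dimension corresponds to one gene program (GP). The decoder is a single
#' linear layer from the latent scores and the condition one-hot to
#' negative-binomial means, `NB(g([Z, C] [W, L]'), C D)`, with
#' `g(x) = softmax(x) * S` by default (`S` the per-cell library size) and a
#' per-condition, per-gene dispersion matrix `D`. The weight matrix `W` is
#' masked by the program membership matrix: hard-membership columns have
#' non-member weights pinned to exactly zero; soft-membership columns leave
#' them free but L1-penalized. Optimization is proximal stochastic gradient
#' descent: plain SGD steps on `W` followed by the closed-form proximal map of
#' the group-lasso plus soft-membership penalty (see [apply_decoder_prox()]),
#' which drives redundant program columns to exactly zero, and Adam steps on
#' the encoder, `L` and `D`. The encoder is a small fully connected network on
#' `log1p` counts concatenated with the condition one-hot.
#'
#' @param counts Nonnegative integer count matrix, cells x genes (dense or
#'   `Matrix` sparse). If it has column names they must match
#'   `mask$gene_names` (reordered by name if necessary).
#' @param conditions Factor/character of per-cell condition (batch) labels, or
#'   `NULL` for a single condition.
#' @param mask A [build_gp_mask()] object defining the gene programs. The
#'   latent dimension equals its number of program columns.
#' @param hidden_sizes Encoder hidden layer widths (default `c(256, 256)`).
#' @param link Decoder inverse link: `"softmax"` (default; means sum to the
#'   library size), `"softplus"` or `"exp"` (positive output multiplied by the
#'   library size).
#' @param alpha_kl Weight on the KL term of the ELBO (default 0.5).
#' @param nu Weight on the HSIC penalty applied to new unconstrained latent
#'   nodes during query mapping; unused (zero) when no such nodes exist.
#' @param prox A [prox_config()] with the group-lasso and L1 strengths.
#' @param epochs Training epochs (default 400).
#' @param batch_size Mini-batch size (default 128, minimum 2).
#' @param lr Adam learning rate for encoder, `L` and `D` (default 1e-3).
#' @param lr_decoder SGD learning rate for `W`; also the `eta` entering every
#'   proximal threshold (default 0.01).
#' @param clip_grad Per-tensor gradient L2-norm clip (default 10), guarding the
#'   plain SGD decoder step against early saturation.
#' @param prox_warmup Fraction of the epochs over which the group-lasso
#'   strength `alpha`, the new-node L1 `gamma_ext` and the KL weight
#'   `alpha_kl` ramp linearly from 0 to their full values (default 0.3;
#'   KL annealing is standard VAE practice). The ramp lets program columns establish
#'   their encoder correlation before the deactivation penalties bite; the
#'   soft-membership strengths `gamma` and `alpha_l1` are applied at full
#'   strength from the first step.
#' @param seed Integer seed; the whole fit is reproducible given it.
#' @param early_stopping Stop when the validation ELBO has not improved for
#'   `patience` epochs and restore the best parameters (default `FALSE`).
#' @param patience Early-stopping patience in epochs (default 25).
#' @param val_fraction Fraction of cells held out for validation when
#'   `early_stopping = TRUE` (stratified by condition, default 0.1).
#' @param verbose Print per-epoch losses and the soft-mask deactivation share.
#' @return An object of class `gpvae` with components `dec` (`W`, `L`, raw log
#'   dispersions `Draw`), `enc`, `mask`, `roles`, `condition_names`,
#'   `program_names`, `gene_names`, `config` and `report` (per-epoch loss
#'   trace, deactivated programs, soft-mask share). Methods: `print`,
#'   `summary`, `coef` (returns `W`), `predict` (latent scores or NB means),
#'   `plot` (loss trace).
#' @seealso [extend_gpvae()], [map_query()], [rank_gps()], [simulate_gp_counts()]
#' @export
gpvae <- function(counts, conditions = NULL, mask,
                  hidden_sizes = c(256L, 256L),
                  link = c("softmax", "softplus", "exp"),
                  alpha_kl = 0.5, nu = 10,
                  prox = prox_config(),
                  epochs = 400L, batch_size = 128L,
                  lr = 1e-3, lr_decoder = 0.01, clip_grad = 10,
                  prox_warmup = 0.3, seed = 1L,
                  early_stopping = FALSE, patience = 25L, val_fraction = 0.1,
                  verbose = FALSE) {
  link <- match.arg(link)
  stopifnot(epochs >= 1L, batch_size >= 2L, lr >= 0, lr_decoder >= 0,
            alpha_kl >= 0, nu >= 0, length(hidden_sizes) >= 1L)
  X <- .as_count_matrix(counts, mask$gene_names)
  n <- nrow(X)
  cond <- .as_conditions(conditions, n)
  roles <- ifelse(mask$membership == "hard", "hard", "soft")
  cfg <- list(alpha_kl = alpha_kl, nu = nu, prox = prox, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = lr, lr_decoder = lr_decoder,
              clip_grad = clip_grad, prox_warmup = prox_warmup,
              seed = as.integer(seed), early_stopping = early_stopping,
              patience = as.integer(patience), val_fraction = val_fraction,
              hidden_sizes = as.integer(hidden_sizes), link = link)

  set.seed(cfg$seed)
  P <- length(mask$program_names)
  G <- length(mask$gene_names)
  K <- nlevels(cond)
  enc <- init_encoder(G + K, cfg$hidden_sizes, P)
  # members start small random; everything outside an annotation starts at
  # exactly zero (soft columns may recruit later through the gradient)
  W0 <- matrix(stats::rnorm(G * P, sd = 0.05), G, P,
               dimnames = list(mask$gene_names, mask$program_names))
  W0[mask$B == 0] <- 0
  dec <- list(
    W = W0,
    L = matrix(0, G, K, dimnames = list(mask$gene_names, levels(cond))),
    Draw = matrix(0, K, G, dimnames = list(levels(cond), mask$gene_names))
  )
  model <- structure(
    list(gene_names = mask$gene_names, program_names = mask$program_names,
         condition_names = levels(cond), mask = mask, roles = roles,
         enc = enc, dec = dec, config = cfg, frozen = NULL,
         hsic_new_idx = integer(0), report = NULL, n_train = n),
    class = "gpvae"
  )
  model <- .train_loop(model, X, cond, cfg, trainable = NULL, verbose = verbose)
  model
}

# ---- input coercion helpers -------------------------------------------------

.as_count_matrix <- function(counts, gene_names) {
  X <- as.matrix(counts)
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), gene_names)) {
      stop("count matrix gene names do not match the mask's gene universe")
    }
    X <- X[, gene_names, drop = FALSE]
  } else if (ncol(X) != length(gene_names)) {
    stop("count matrix has ", ncol(X), " genes but the mask has ",
         length(gene_names))
  }
  if (any(X < 0)) stop("counts must be nonnegative")
  if (any(abs(X - round(X)) > 1e-8)) {
    stop("counts must be raw integers; normalized input cannot be modeled ",
         "with the negative-binomial likelihood")
  }
  storage.mode(X) <- "double"
  X
}

.as_conditions <- function(conditions, n, levels = NULL) {
  if (is.null(conditions)) conditions <- rep("cond1", n)
  if (length(conditions) != n) stop("conditions must have one label per cell")
  if (is.null(levels)) factor(as.character(conditions))
  else {
    f <- factor(as.character(conditions), levels = levels)
    if (anyNA(f)) {
      stop("unknown condition label(s): ",
           paste(unique(conditions[is.na(f)]), collapse = ", "))
    }
    f
  }
}

.one_hot <- function(cond) {
  C <- matrix(0, length(cond), nlevels(cond),
              dimnames = list(NULL, levels(cond)))
  C[cbind(seq_along(cond), as.integer(cond))] <- 1
  C
}

# ---- decoder ----------------------------------------------------------------

#' Decode latent scores to negative-binomial means
#'
#' Computes the linear pre-activation `H = [Z, C] [W, L]'` and applies the
#' inverse link: with `link = "softmax"` the mean is `softmax(H) * S` so every
#' cell's means sum exactly to its library size `S`; with `"softplus"` or
#' `"exp"` the positive transform of `H` is multiplied by `S`.
#'
#' @param Z Latent score matrix, cells x programs.
#' @param C One-hot condition matrix, cells x conditions.
#' @param W Decoder program weights, genes x programs.
#' @param L Decoder condition weights, genes x conditions.
#' @param library_size Positive per-cell library sizes.
#' @param link `"softmax"`, `"softplus"` or `"exp"`.
#' @return Matrix of NB means, cells x genes.
#' @export
decode_nb_mean <- function(Z, C, W, L, library_size,
                           link = c("softmax", "softplus", "exp")) {
  link <- match.arg(link)
  stopifnot(ncol(Z) == ncol(W), ncol(C) == ncol(L), all(library_size > 0))
  H <- tcrossprod(Z, W) + tcrossprod(C, L)
  if (any(!is.finite(H))) {
    stop("non-finite decoder pre-activation for cell ",
         which(!is.finite(rowSums(H)))[1])
  }
  mu <- switch(link,
    softmax = {
      E <- exp(H - apply(H, 1L, max))
      (E / rowSums(E)) * library_size
    },
    softplus = .softplus(H) * library_size,
    exp = exp(H) * library_size
  )
  pmax(mu, 1e-10)
}

# per-cell dispersion matrix from the raw log-dispersion table
.theta_for <- function(Draw, cond_idx) {
  exp(Draw[cond_idx, , drop = FALSE])
}

#' Loss components of the model on a batch of cells
#'
#' Evaluates the pieces of the training objective: the negative-binomial
#' reconstruction term, the KL divergence of the latent posterior from the
#' standard-normal prior, and the HSIC penalty over new unconstrained nodes
#' (exactly zero when none exist). The group-lasso and soft-membership
#' penalties are enforced by the proximal step and are deliberately not part
#' of this differentiable loss. `total = recon + alpha_kl * kl + nu * hsic`.
#'
#' @param model A fitted or in-training `gpvae` object.
#' @param counts Count matrix, cells x genes.
#' @param conditions Per-cell condition labels (must be known to the model).
#' @param alpha_kl,nu Weights; default to the model's configuration.
#' @param sample Use a reparameterized latent draw (`TRUE`) or the posterior
#'   mean (`FALSE`, default, deterministic).
#' @return Named list `recon`, `kl`, `hsic`, `total` (per-cell averages).
#' @export
loss_components <- function(model, counts, conditions = NULL,
                            alpha_kl = model$config$alpha_kl,
                            nu = model$config$nu, sample = FALSE) {
  X <- .as_count_matrix(counts, model$gene_names)
  cond <- .as_conditions(conditions, nrow(X), model$condition_names)
  C <- .one_hot(cond)
  fwd <- encoder_forward(model$enc, cbind(log1p(X), C))
  Z <- if (sample) {
    fwd$mu + sqrt(fwd$sigma2) * matrix(stats::rnorm(length(fwd$mu)), nrow(fwd$mu))
  } else fwd$mu
  S <- rowSums(X)
  mu_nb <- decode_nb_mean(Z, C, model$dec$W, model$dec$L, S, model$config$link)
  theta <- .theta_for(model$dec$Draw, as.integer(cond))
  recon <- -mean(nb_loglik(X, mu_nb, theta))
  kl <- mean(kl_gaussian(fwd$mu, fwd$sigma2))
  h <- if (length(model$hsic_new_idx) > 0L && nrow(Z) >= 4L) {
    hsic_total(Z, model$hsic_new_idx)
  } else 0
  list(recon = recon, kl = kl, hsic = h, total = recon + alpha_kl * kl + nu * h)
}

# ---- training loop ----------------------------------------------------------

# One mini-batch: loss components and analytic gradients of the
# differentiable objective (reconstruction + alpha_kl * KL + nu * HSIC) with
# respect to every parameter tensor, using the reparameterized draw
# Z = mu + sqrt(sigma2) * eps. The group-lasso / soft-mask penalties are not
# differentiated; they enter through the proximal step only.
.batch_grads <- function(model, Xb, logXb, Cb, cb, Sb, cfg, eps, hsic_idx) {
  nb <- nrow(Xb)
  fwd <- encoder_forward(model$enc, cbind(logXb, Cb))
  sd_ <- sqrt(fwd$sigma2)
  Z <- fwd$mu + sd_ * eps

  Hd <- tcrossprod(Z, model$dec$W) + tcrossprod(Cb, model$dec$L)
  theta <- .theta_for(model$dec$Draw, cb)
  if (cfg$link == "softmax") {
    E <- exp(Hd - apply(Hd, 1L, max))
    Pm <- E / rowSums(E)
    mu_nb <- pmax(Pm * Sb, 1e-10)
  } else if (cfg$link == "softplus") {
    mu_nb <- pmax(.softplus(Hd) * Sb, 1e-10)
  } else {
    mu_nb <- pmax(exp(Hd) * Sb, 1e-10)
  }

  recon <- -mean(nb_loglik(Xb, mu_nb, theta))
  klv <- mean(kl_gaussian(fwd$mu, fwd$sigma2))
  ht <- .hsic_terms(Z, if (nb >= 4L) hsic_idx else integer(0), grad = TRUE)
  hv <- ht$value
  total <- recon + cfg$alpha_kl * klv + cfg$nu * hv

  a <- Xb / mu_nb - (Xb + theta) / (theta + mu_nb)
  dH <- if (cfg$link == "softmax") {
    am <- a * mu_nb
    -(am - Pm * rowSums(am)) / nb
  } else if (cfg$link == "softplus") {
    -(a * .sigmoid(Hd) * Sb) / nb
  } else {
    -(a * mu_nb) / nb
  }
  gW <- crossprod(dH, Z)
  gL <- crossprod(dH, Cb)
  dth <- digamma(Xb + theta) - digamma(theta) +
    log(theta / (theta + mu_nb)) + (mu_nb - Xb) / (theta + mu_nb)
  gDraw <- -crossprod(Cb, dth * theta) / nb

  dz <- dH %*% model$dec$W
  if (length(hsic_idx) > 0L && nb >= 4L) {
    dz <- dz + cfg$nu * ht$grad
  }
  dmu <- dz + cfg$alpha_kl * fwd$mu / nb
  ds2 <- dz * eps * (0.5 / sd_) +
    cfg$alpha_kl * 0.5 * (1 - 1 / fwd$sigma2) / nb
  genc <- encoder_backward(model$enc, fwd, dmu, ds2)

  list(recon = recon, kl = klv, hsic = hv, total = total,
       gW = gW, gL = gL, gDraw = gDraw, genc = genc)
}

# rescale a gradient tensor so its global L2 norm is at most max_norm;
# guards the plain-SGD decoder step against the saturation feedback loop
# (large W -> saturated softmax -> clamped means -> exploding gradients)
.clip_grad <- function(g, max_norm) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > max_norm) g * (max_norm / nrm) else g
}

# trainable = NULL trains everything (reference); otherwise a partition list
# created by map_query() restricting updates to the extension tensors.
.train_loop <- function(model, X, cond, cfg, trainable, verbose = FALSE) {
  set.seed(cfg$seed)
  n <- nrow(X)
  cid <- as.integer(cond)
  C <- .one_hot(cond)
  S <- rowSums(X)
  logX <- log1p(X)

  val_idx <- integer(0)
  if (cfg$early_stopping && cfg$val_fraction > 0) {
    val_idx <- unlist(lapply(split(seq_len(n), cid), function(ix) {
      k <- max(1L, round(length(ix) * cfg$val_fraction))
      sample(ix, min(k, length(ix)))
    }), use.names = FALSE)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  adam <- list(enc = NULL, L = NULL, Draw = NULL)
  adam$L <- list(m = model$dec$L * 0, v = model$dec$L * 0)
  adam$Draw <- list(m = model$dec$Draw * 0, v = model$dec$Draw * 0)
  flat_enc <- .enc_flatten(model$enc)
  adam$enc <- lapply(flat_enc, function(p) list(m = p * 0, v = p * 0))
  step <- 0L

  trace <- matrix(NA_real_, cfg$epochs, 5L,
                  dimnames = list(NULL, c("recon", "kl", "hsic", "total", "val")))
  best <- NULL
  best_val <- Inf
  bad <- 0L
  hsic_idx <- model$hsic_new_idx
  use_hsic <- length(hsic_idx) > 0L && cfg$nu > 0
  epochs_run <- 0L

  warmup_epochs <- max(0L, ceiling(cfg$prox_warmup * cfg$epochs))
  for (ep in seq_len(cfg$epochs)) {
    ramp <- if (warmup_epochs > 0L) min(1, ep / warmup_epochs) else 1
    prox_ep <- cfg$prox
    prox_ep$alpha <- ramp * prox_ep$alpha
    prox_ep$gamma_ext <- ramp * prox_ep$gamma_ext
    cfg_ep <- cfg
    cfg_ep$alpha_kl <- ramp * cfg$alpha_kl   # KL annealing over the warm-up
    perm <- sample(train_idx)
    acc <- c(recon = 0, kl = 0, hsic = 0, total = 0)
    nb_cells <- 0L
    starts <- seq(1L, length(perm), by = cfg$batch_size)
    for (s in starts) {
      ix <- perm[s:min(s + cfg$batch_size - 1L, length(perm))]
      if (length(ix) < 2L) next
      step <- step + 1L
      nb <- length(ix)
      Xb <- X[ix, , drop = FALSE]
      Cb <- C[ix, , drop = FALSE]
      cb <- cid[ix]
      Sb <- S[ix]

      eps <- matrix(stats::rnorm(nb * length(model$program_names)), nb)
      gr <- .batch_grads(model, Xb, logX[ix, , drop = FALSE], Cb, cb, Sb,
                         cfg_ep, eps, if (use_hsic) hsic_idx else integer(0))
      recon <- gr$recon; klv <- gr$kl; hv <- gr$hsic; total <- gr$total
      if (!is.finite(total)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", batch ", which(starts == s))
      }
      gW <- gr$gW; gL <- gr$gL; gDraw <- gr$gDraw; genc <- gr$genc

      if (!is.null(trainable)) {
        genc <- .mask_enc_grads(genc, trainable)
        gW[, trainable$frozen_w_cols] <- 0
        gL[, trainable$frozen_l_cols] <- 0
        gDraw[trainable$frozen_d_rows, ] <- 0
      }

      # Adam on encoder, L, D
      gW <- .clip_grad(gW, cfg$clip_grad)
      gL <- .clip_grad(gL, cfg$clip_grad)
      gDraw <- .clip_grad(gDraw, cfg$clip_grad)
      genc <- rapply(genc, function(g) .clip_grad(g, cfg$clip_grad),
                     how = "replace")
      gflat <- .enc_flatten(genc)
      pflat <- .enc_flatten(model$enc)
      for (k in names(pflat)) {
        up <- adam_step(pflat[[k]], gflat[[k]], adam$enc[[k]], cfg$lr, step)
        pflat[[k]] <- up$param
        adam$enc[[k]] <- up$state
      }
      model$enc <- .enc_unflatten(pflat, model$enc)
      up <- adam_step(model$dec$L, gL, adam$L, cfg$lr, step)
      model$dec$L <- up$param; adam$L <- up$state
      up <- adam_step(model$dec$Draw, gDraw, adam$Draw, cfg$lr, step)
      model$dec$Draw <- up$param; adam$Draw <- up$state

      # plain SGD + proximal map on W
      Wn <- model$dec$W - cfg$lr_decoder * gW
      model$dec$W <- apply_decoder_prox(
        Wn, model$mask$M, model$roles, cfg$lr_decoder, prox_ep,
        frozen_cols = if (!is.null(trainable)) trainable$frozen_w_cols else NULL
      )

      acc <- acc + nb * c(recon = recon, kl = klv, hsic = hv, total = total)
      nb_cells <- nb_cells + nb
    }
    trace[ep, 1:4] <- acc / nb_cells
    epochs_run <- ep

    if (length(val_idx) > 0L) {
      vl <- .val_loss(model, X, logX, C, cid, S, val_idx, cfg)
      trace[ep, "val"] <- vl
      if (vl < best_val - 1e-6) {
        best_val <- vl
        best <- list(enc = model$enc, dec = model$dec)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) {
          if (verbose) message("early stop at epoch ", ep)
          break
        }
      }
    }
    if (verbose && (ep %% 25L == 0L || ep == 1L)) {
      message(sprintf(
        "epoch %d | recon %.2f kl %.3f hsic %.4f total %.2f | share of de-activated inactive genes in extension terms: %.3f",
        ep, trace[ep, 1], trace[ep, 2], trace[ep, 3], trace[ep, 4],
        suppressWarnings(inactive_gene_share(model))))
    }
  }
  if (!is.null(best)) {
    model$enc <- best$enc
    model$dec <- best$dec
  }

  tr <- as.data.frame(trace[seq_len(epochs_run), , drop = FALSE])
  tr <- cbind(epoch = seq_len(epochs_run), tr)
  model$report <- structure(
    list(trace = tr,
         deactivated_programs = deactivated_gps(model),
         inactive_gene_deactivation_share =
           suppressWarnings(inactive_gene_share(model)),
         epochs_run = epochs_run),
    class = "gpvae_report"
  )
  model
}

.val_loss <- function(model, X, logX, C, cid, S, val_idx, cfg) {
  fwd <- encoder_forward(model$enc,
                         cbind(logX[val_idx, , drop = FALSE],
                               C[val_idx, , drop = FALSE]))
  mu_nb <- decode_nb_mean(fwd$mu, C[val_idx, , drop = FALSE], model$dec$W,
                          model$dec$L, S[val_idx], cfg$link)
  theta <- .theta_for(model$dec$Draw, cid[val_idx])
  -mean(nb_loglik(X[val_idx, , drop = FALSE], mu_nb, theta)) +
    cfg$alpha_kl * mean(kl_gaussian(fwd$mu, fwd$sigma2))
}

# encoder tensors as a flat named list (for generic optimizer bookkeeping)
.enc_flatten <- function(enc) {
  out <- list(Wmu = enc$Wmu, bmu = enc$bmu, Ws = enc$Ws, bs = enc$bs)
  for (l in seq_along(enc$W)) {
    out[[paste0("W", l)]] <- enc$W[[l]]
    out[[paste0("b", l)]] <- enc$b[[l]]
  }
  out
}

.enc_unflatten <- function(flat, enc) {
  enc$Wmu <- flat$Wmu; enc$bmu <- flat$bmu
  enc$Ws <- flat$Ws; enc$bs <- flat$bs
  for (l in seq_along(enc$W)) {
    enc$W[[l]] <- flat[[paste0("W", l)]]
    enc$b[[l]] <- flat[[paste0("b", l)]]
  }
  enc
}

# zero the gradients of all frozen encoder entries during query training:
# only new condition input rows of layer 1 and the output-head columns of the
# new latent nodes stay trainable
.mask_enc_grads <- function(genc, trainable) {
  g1 <- genc$W[[1]]
  g1[trainable$frozen_in_rows, ] <- 0
  genc$W[[1]] <- g1
  for (l in seq_along(genc$W)[-1]) genc$W[[l]][] <- 0
  for (l in seq_along(genc$b)) genc$b[[l]][] <- 0
  genc$Wmu[, trainable$frozen_p_cols] <- 0
  genc$bmu[trainable$frozen_p_cols] <- 0
  genc$Ws[, trainable$frozen_p_cols] <- 0
  genc$bs[trainable$frozen_p_cols] <- 0
  genc
}

# ---- diagnostics ------------------------------------------------------------

#' Deactivated gene programs
#'
#' Program columns whose decoder weights have L2 norm at most `tol`. The
#' group-lasso proximal map produces exact zeros, so the default `tol = 0` is
#' meaningful: a deactivated program is bitwise zero.
#'
#' @param model A `gpvae` object.
#' @param tol Nonnegative norm tolerance (default 0).
#' @return Character vector of program names.
#' @export
deactivated_gps <- function(model, tol = 0) {
  nrm <- sqrt(colSums(model$dec$W^2))
  model$program_names[nrm <= tol]
}

#' Share of de-activated inactive genes in soft-masked programs
#'
#' Among decoder entries that lie outside their program's annotation
#' (`M = 1`) in soft-membership columns (including new constrained soft
#' columns added at query time), the fraction whose weight is exactly zero.
#' A healthy fit keeps this above 0.9; lower values mean the soft programs
#' lost their annotated specialization — increase the soft-mask strength and
#' retrain.
#'
#' @param model A `gpvae` object.
#' @return A number in `[0, 1]`; returns 1 with a warning when the model has
#'   no soft-masked entries.
#' @export
inactive_gene_share <- function(model) {
  softish <- model$roles %in% c("soft", "new_constrained_soft")
  if (!any(softish)) {
    warning("model has no soft-masked columns; share is trivially 1")
    return(1)
  }
  Msub <- model$mask$M[, softish, drop = FALSE]
  Wsub <- model$dec$W[, softish, drop = FALSE]
  idx <- Msub != 0
  if (!any(idx)) {
    warning("soft-masked columns have no penalized entries; share is trivially 1")
    return(1)
  }
  mean(Wsub[idx] == 0)
}

# ---- S3 interface -----------------------------------------------------------

#' Posterior parameters of the latent gene-program scores
#'
#' Runs the encoder on a set of cells and returns the per-cell diagonal
#' Gaussian posterior over the latent program scores.
#'
#' @param model A `gpvae` object.
#' @param counts Count matrix, cells x genes.
#' @param conditions Per-cell condition labels known to the model.
#' @return List with matrices `mu` and `sigma2` (cells x programs, columns
#'   named by program).
#' @export
posterior_params <- function(model, counts, conditions = NULL) {
  X <- .as_count_matrix(counts, model$gene_names)
  cond <- .as_conditions(conditions, nrow(X), model$condition_names)
  fwd <- encoder_forward(model$enc, cbind(log1p(X), .one_hot(cond)))
  mu <- fwd$mu; sigma2 <- fwd$sigma2
  colnames(mu) <- colnames(sigma2) <- model$program_names
  rownames(mu) <- rownames(sigma2) <- rownames(X)
  list(mu = mu, sigma2 = sigma2)
}

#' Latent gene-program scores for cells
#'
#' Posterior means of the latent program scores (the quantity used for all
#' downstream program-level analysis), optionally sign-aligned so that higher
#' scores correspond to predominant upregulation (see [gp_direction()]).
#'
#' @inheritParams posterior_params
#' @param directed Multiply each column by its program direction.
#' @param direction_method `"sum"` or `"counts"`; see [gp_direction()].
#' @return Matrix of latent scores, cells x programs.
#' @export
latent_scores <- function(model, counts, conditions = NULL, directed = FALSE,
                          direction_method = c("sum", "counts")) {
  mu <- posterior_params(model, counts, conditions)$mu
  if (directed) {
    direction_method <- match.arg(direction_method)
    d <- vapply(seq_len(ncol(model$dec$W)),
                function(j) gp_direction(model$dec$W[, j], direction_method),
                numeric(1))
    mu <- directed_scores(mu, d)
  }
  mu
}

#' @export
predict.gpvae <- function(object, counts, conditions = NULL,
                          type = c("latent", "response"),
                          library_size = NULL, directed = FALSE, ...) {
  type <- match.arg(type)
  if (type == "latent") {
    return(latent_scores(object, counts, conditions, directed = directed))
  }
  X <- .as_count_matrix(counts, object$gene_names)
  cond <- .as_conditions(conditions, nrow(X), object$condition_names)
  C <- .one_hot(cond)
  mu <- posterior_params(object, counts, conditions)$mu
  if (is.null(library_size)) library_size <- rowSums(X)
  out <- decode_nb_mean(mu, C, object$dec$W, object$dec$L, library_size,
                        object$config$link)
  dimnames(out) <- list(rownames(X), object$gene_names)
  out
}

#' @export
coef.gpvae <- function(object, ...) object$dec$W

#' @export
print.gpvae <- function(x, ...) {
  cat("Gene-program conditional VAE (", length(x$gene_names), " genes, ",
      length(x$program_names), " programs, ", length(x$condition_names),
      " conditions)\n", sep = "")
  cat("  link:", x$config$link,
      "| alpha_kl:", x$config$alpha_kl,
      "| group lasso alpha:", x$config$prox$alpha, "\n")
  if (!is.null(x$report)) {
    cat("  epochs run:", x$report$epochs_run,
        "| final loss:", round(utils::tail(x$report$trace$total, 1), 2), "\n")
    cat("  deactivated programs:", length(x$report$deactivated_programs),
        "of", length(x$program_names), "\n")
  }
  if (!is.null(x$frozen)) {
    cat("  query-mapped model:", x$frozen$n_old_programs, "reference +",
        length(x$program_names) - x$frozen$n_old_programs, "new programs\n")
  }
  invisible(x)
}

#' @export
summary.gpvae <- function(object, ...) {
  print(object)
  cat("\nProgram column norms:\n")
  nrm <- sqrt(colSums(object$dec$W^2))
  print(summary(nrm))
  da <- deactivated_gps(object)
  if (length(da)) {
    cat("\nDeactivated:", paste(utils::head(da, 10L), collapse = ", "),
        if (length(da) > 10L) "..." else "", "\n")
  }
  softish <- any(object$roles != "hard")
  if (softish) {
    cat("\nShare of de-activated inactive genes in extension terms:",
        round(inactive_gene_share(object), 3), "\n")
  }
  invisible(object)
}

#' @export
plot.gpvae <- function(x, ...) {
  tr <- x$report$trace
  graphics::matplot(tr$epoch, cbind(tr$recon, tr$total), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss",
                    col = c("grey50", "black"), ...)
  graphics::legend("topright", c("reconstruction", "total"), lty = 1,
                   col = c("grey50", "black"), bty = "n")
  invisible(x)
}

#' @export
print.gpvae_report <- function(x, ...) {
  cat("Training report:", x$epochs_run, "epochs\n")
  cat("  final losses:",
      paste(names(x$trace)[-1],
            round(unlist(utils::tail(x$trace, 1))[-1], 3),
            sep = "=", collapse = " "), "\n")
  cat("  deactivated programs:", length(x$deactivated_programs), "\n")
  cat("  share of de-activated inactive genes in extension terms:",
      round(x$inactive_gene_deactivation_share, 3), "\n")
  invisible(x)
}
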