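#' Extend a trained reference model for query mapping
#'
#' Architecture surgery: grows a trained reference `gpvae` with new condition
#' inputs and, optionally, new latent program nodes, producing a partitioned
#' model in which every reference tensor is frozen and only the additions are
#' trainable. New unconstrained nodes carry a plain L1 penalty (`gamma_ext`)
#' and, by default, an HSIC penalty pushing them towards independence from all
#' other latent dimensions; new constrained nodes are wired to a user-supplied
#' gene-program mask over the same gene axis and are never HSIC-regularized.
#' All new decoder weights and new condition columns are zero-initialized, so
#' the latent representation and reconstruction of any reference cell are
#' bit-identical before query training; new encoder-head columns get small
#' random initial weights.
#'
#' @param model A trained reference `gpvae`.
#' @param new_conditions Character vector of query condition labels (must not
#'   collide with reference conditions).
#' @param n_new_unconstrained Number of new unconstrained sparse program nodes
#'   (default 10; redundant ones are switched off by the L1 penalty).
#' @param new_constrained Optional `gp_mask` built on the same `gene_names`
#'   defining new constrained programs (names must be new).
#' @param hsic_on_new Apply the HSIC penalty to the new unconstrained nodes
#'   during query training (default `TRUE`).
#' @param init_sd Standard deviation of the random initialization of the new
#'   encoder-head columns (default 0.01).
#' @param seed Seed for the new-weight initialization.
#' @return A `gpvae` object with a `frozen` partition descriptor; pass it to
#'   [map_query()].
#' @export
extend_gpvae <- function(model, new_conditions = character(),
                         n_new_unconstrained = 10L, new_constrained = NULL,
                         hsic_on_new = TRUE, init_sd = 0.01, seed = 1L) {
  stopifnot(inherits(model, "gpvae"))
  if (!is.null(model$frozen)) stop("model has already been extended")
  if (any(new_conditions %in% model$condition_names)) {
    stop("new condition name collides with a reference condition: ",
         paste(intersect(new_conditions, model$condition_names), collapse = ", "))
  }
  n_con <- 0L
  con_names <- character(0)
  if (!is.null(new_constrained)) {
    if (!identical(new_constrained$gene_names, model$gene_names)) {
      stop("new_constrained must be built on the model's gene_names, in order")
    }
    if (any(new_constrained$program_names %in% model$program_names)) {
      stop("new constrained program name collides with a reference program")
    }
    n_con <- length(new_constrained$program_names)
    con_names <- new_constrained$program_names
  }
  n_new <- n_con + n_new_unconstrained
  unc_names <- if (n_new_unconstrained > 0L) {
    sprintf("new_unconstrained_%02d", seq_len(n_new_unconstrained))
  } else character(0)

  set.seed(seed)
  G <- length(model$gene_names)
  P_old <- length(model$program_names)
  K_old <- length(model$condition_names)

  # decoder: zero-initialized new program columns and condition columns
  if (n_new > 0L) {
    Wn <- matrix(0, G, n_new, dimnames = list(model$gene_names,
                                              c(con_names, unc_names)))
    model$dec$W <- cbind(model$dec$W, Wn)
    Bn <- matrix(0, G, n_new)
    Mn <- matrix(1, G, n_new)
    if (n_con > 0L) {
      Bn[, seq_len(n_con)] <- new_constrained$B
      Mn[, seq_len(n_con)] <- new_constrained$M
    }
    model$mask$B <- cbind(model$mask$B, Bn)
    model$mask$M <- cbind(model$mask$M, Mn)
    colnames(model$mask$B) <- colnames(model$mask$M) <-
      c(model$program_names, con_names, unc_names)
    con_roles <- if (n_con > 0L) {
      ifelse(new_constrained$membership == "soft",
             "new_constrained_soft", "new_constrained_hard")
    } else character(0)
    model$roles <- c(model$roles, con_roles, rep("new_unconstrained", n_new_unconstrained))
    model$mask$membership <- c(model$mask$membership,
                               if (n_con > 0L) new_constrained$membership else character(0),
                               rep("unconstrained", n_new_unconstrained))
    model$mask$program_names <- colnames(model$mask$B)
  }
  if (length(new_conditions) > 0L) {
    Ln <- matrix(0, G, length(new_conditions),
                 dimnames = list(model$gene_names, new_conditions))
    model$dec$L <- cbind(model$dec$L, Ln)
    # new-condition dispersions start at the mean reference log dispersion
    Dn <- matrix(rep(colMeans(model$dec$Draw), each = length(new_conditions)),
                 nrow = length(new_conditions),
                 dimnames = list(new_conditions, model$gene_names))
    model$dec$Draw <- rbind(model$dec$Draw, Dn)
    # encoder input grows by the new condition one-hot dims (zero-initialized)
    model$enc$W[[1]] <- rbind(model$enc$W[[1]],
                              matrix(0, length(new_conditions),
                                     ncol(model$enc$W[[1]])))
  }
  if (n_new > 0L) {
    h_out <- length(model$enc$bmu)
    h_dim <- nrow(model$enc$Wmu)
    model$enc$Wmu <- cbind(model$enc$Wmu,
                           matrix(stats::rnorm(h_dim * n_new, sd = init_sd), h_dim))
    model$enc$Ws <- cbind(model$enc$Ws,
                          matrix(stats::rnorm(h_dim * n_new, sd = init_sd), h_dim))
    model$enc$bmu <- c(model$enc$bmu, rep(0, n_new))
    model$enc$bs <- c(model$enc$bs, rep(0, n_new))
  }

  model$program_names <- c(model$program_names, con_names, unc_names)
  model$condition_names <- c(model$condition_names, new_conditions)
  new_prog_idx <- if (n_new > 0L) P_old + seq_len(n_new) else integer(0)
  unc_idx <- if (n_new_unconstrained > 0L) {
    P_old + n_con + seq_len(n_new_unconstrained)
  } else integer(0)
  model$hsic_new_idx <- if (hsic_on_new) unc_idx else integer(0)
  model$frozen <- list(
    n_old_programs = P_old,
    n_old_conditions = K_old,
    n_old_inputs = G + K_old,
    new_prog_idx = new_prog_idx,
    new_cond_idx = if (length(new_conditions) > 0L) {
      K_old + seq_along(new_conditions)
    } else integer(0)
  )
  model$report <- NULL
  model
}

# tensors that must stay bit-identical through query training
frozen_tensors <- function(model) {
  fr <- model$frozen
  stopifnot(!is.null(fr))
  enc <- model$enc
  list(
    W_old = model$dec$W[, seq_len(fr$n_old_programs), drop = FALSE],
    L_old = model$dec$L[, seq_len(fr$n_old_conditions), drop = FALSE],
    Draw_old = model$dec$Draw[seq_len(fr$n_old_conditions), , drop = FALSE],
    enc_in_old = enc$W[[1]][seq_len(fr$n_old_inputs), , drop = FALSE],
    enc_hidden = enc$W[-1],
    enc_biases = enc$b,
    Wmu_old = enc$Wmu[, seq_len(fr$n_old_programs), drop = FALSE],
    Ws_old = enc$Ws[, seq_len(fr$n_old_programs), drop = FALSE],
    bmu_old = enc$bmu[seq_len(fr$n_old_programs)],
    bs_old = enc$bs[seq_len(fr$n_old_programs)]
  )
}

#' Checksum of a model's frozen reference partition
#'
#' MD5 digest of the serialized frozen tensors of an extended model; identical
#' before and after [map_query()] by construction (and asserted there).
#'
#' @param model An extended `gpvae`.
#' @return Character MD5 digest.
#' @export
frozen_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(frozen_tensors(model), f, version = 3L)
  unname(tools::md5sum(f))
}

#' Fine-tune an extended model on query data
#'
#' Trains only the extension partition of an [extend_gpvae()] model on query
#' cells: the condition weights of the new batches (encoder input rows, `L`
#' columns and dispersion rows) and the encoder/decoder weights of the new
#' program nodes. Every reference tensor is frozen and verified bit-identical
#' after training. New unconstrained nodes receive the HSIC penalty against
#' all other latent dimensions (weight `nu`) and an L1 proximal step
#' (`gamma_ext`); new constrained soft nodes get the masked L1 (`alpha_l1`).
#' Reference cells are not replayed.
#'
#' @param model An extended `gpvae`.
#' @param counts Query count matrix, cells x genes.
#' @param conditions Query condition labels; must all be new conditions (a
#'   query carrying a reference condition label must be mapped as a new
#'   condition instead).
#' @param epochs Query training epochs (default 200).
#' @param batch_size,lr,lr_decoder,nu,alpha_kl,prox,seed,early_stopping,patience,val_fraction,verbose
#'   As in [gpvae()]; defaults are inherited from the reference configuration
#'   except `epochs` and `early_stopping` (default `TRUE`, the recommended
#'   query protocol).
#' @return The fine-tuned `gpvae` with an updated training report.
#' @export
map_query <- function(model, counts, conditions, epochs = 200L,
                      batch_size = model$config$batch_size,
                      lr = model$config$lr, lr_decoder = model$config$lr_decoder,
                      nu = model$config$nu, alpha_kl = model$config$alpha_kl,
                      prox = model$config$prox, seed = 1L,
                      early_stopping = TRUE, patience = 25L, val_fraction = 0.1,
                      verbose = FALSE) {
  fr <- model$frozen
  if (is.null(fr)) stop("model has not been extended; call extend_gpvae() first")
  X <- .as_count_matrix(counts, model$gene_names)
  ref_conds <- model$condition_names[seq_len(fr$n_old_conditions)]
  if (any(conditions %in% ref_conds)) {
    stop("query contains reference condition label(s): ",
         paste(intersect(unique(conditions), ref_conds), collapse = ", "),
         "; map query batches under new condition names")
  }
  cond <- .as_conditions(conditions, nrow(X), model$condition_names)

  cfg <- model$config
  cfg$epochs <- as.integer(epochs)
  cfg$batch_size <- as.integer(batch_size)
  cfg$lr <- lr; cfg$lr_decoder <- lr_decoder
  cfg$nu <- nu; cfg$alpha_kl <- alpha_kl; cfg$prox <- prox
  cfg$seed <- as.integer(seed)
  cfg$early_stopping <- early_stopping
  cfg$patience <- as.integer(patience)
  cfg$val_fraction <- val_fraction

  trainable <- list(
    frozen_in_rows = seq_len(fr$n_old_inputs),
    frozen_p_cols = seq_len(fr$n_old_programs),
    frozen_w_cols = seq_len(fr$n_old_programs),
    frozen_l_cols = seq_len(fr$n_old_conditions),
    frozen_d_rows = seq_len(fr$n_old_conditions)
  )
  before <- frozen_checksum(model)
  model <- .train_loop(model, X, cond, cfg, trainable = trainable,
                       verbose = verbose)
  if (!identical(before, frozen_checksum(model))) {
    stop("internal error: frozen reference tensors changed during query training")
  }
  model$config <- cfg
  model
}
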