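#' Probability that one cell's latent score exceeds another's
#'
#' Closed-form probability `P(Z1 > Z2)` for two independent Gaussian
#' posteriors over one latent program score,
#' `0.5 * erfc(-(mu1 - mu2) / sqrt(2 (s1 + s2)))`.
#'
#' @param mu1,mu2 Posterior means (vectorized).
#' @param s1,s2 Posterior variances, strictly positive.
#' @return Probabilities in `(0, 1)`.
#' @examples
#' pairwise_h0_prob(0, 1, 0, 1)   # 0.5
#' @export
pairwise_h0_prob <- function(mu1, s1, mu2, s2) {
  stopifnot(all(s1 > 0), all(s2 > 0))
  stats::pnorm((mu1 - mu2) / sqrt(s1 + s2))
}

#' Log-Bayes factor for one latent program between two cell groups
#'
#' Tests `H0: Z_a > Z_b` against its complement for a single latent dimension.
#' `p(H0)` is the average over random cell pairs (one from each group, drawn
#' with replacement and evaluated symmetrically in both group orders) of the
#' pairwise exceedance probability, computed in closed form from the Gaussian
#' posteriors or by Monte-Carlo draws;
#' `log K = log(p / (1 - p))` with `p` clipped away from 0 and 1 to keep the
#' score finite.
#'
#' @param mu_a,s2_a Posterior means and variances of the program score for the
#'   cells of group a.
#' @param mu_b,s2_b Same for group b.
#' @param n_pairs Number of random cell pairs (default 10000).
#' @param method `"closed_form"` (default) or `"sampling"`.
#' @param n_draws Monte-Carlo draws per pair for `method = "sampling"`.
#' @param clip Probability clipping bound (default 1e-7, giving
#'   `|log K| <= 16.1`).
#' @param seed Seed making the random pairing reproducible.
#' @return List with `p_h0` and `log_bayes_factor`.
#' @export
gp_bayes_factor <- function(mu_a, s2_a, mu_b, s2_b, n_pairs = 10000L,
                            method = c("closed_form", "sampling"),
                            n_draws = 500L, clip = 1e-7, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(mu_a) > 0L, length(mu_b) > 0L, clip > 0, clip < 0.5)
  # Pairing is drawn as seeded uniform coordinates and evaluated in both group
  # orders, then averaged: p(a,b) and p(b,a) use the same coordinates, so
  # swapping the groups yields exactly 1 - p (log K antisymmetry), and testing
  # a group against itself yields exactly 1/2.
  set.seed(seed)
  u <- stats::runif(n_pairs)
  v <- stats::runif(n_pairs)
  pick <- function(w, n) pmin(floor(w * n) + 1L, n)
  i1 <- pick(u, length(mu_a)); j1 <- pick(v, length(mu_b))
  i2 <- pick(u, length(mu_b)); j2 <- pick(v, length(mu_a))
  if (method == "closed_form") {
    m1 <- mean(pairwise_h0_prob(mu_a[i1], s2_a[i1], mu_b[j1], s2_b[j1]))
    m2 <- mean(pairwise_h0_prob(mu_b[i2], s2_b[i2], mu_a[j2], s2_a[j2]))
  } else {
    w1 <- 0; w2 <- 0
    for (d in seq_len(n_draws)) {
      w1 <- w1 + sum(stats::rnorm(n_pairs, mu_a[i1], sqrt(s2_a[i1])) >
                       stats::rnorm(n_pairs, mu_b[j1], sqrt(s2_b[j1])))
      w2 <- w2 + sum(stats::rnorm(n_pairs, mu_b[i2], sqrt(s2_b[i2])) >
                       stats::rnorm(n_pairs, mu_a[j2], sqrt(s2_a[j2])))
    }
    m1 <- w1 / (n_draws * n_pairs)
    m2 <- w2 / (n_draws * n_pairs)
  }
  p <- (m1 + 1 - m2) / 2
  p <- min(max(p, clip), 1 - clip)
  list(p_h0 = p, log_bayes_factor = log(p / (1 - p)))
}

#' Rank gene programs by differential activity between two cell groups
#'
#' Computes the latent posterior for all cells, then for every active program
#' (deactivated, exactly-zero decoder columns are excluded) the log-Bayes
#' factor of `H0: Z_a > Z_b` between the two groups, the program direction,
#' and an enrichment flag at `|log K| >= threshold` (default 2.3, i.e. one
#' hypothesis 10 times more probable than the other).
#'
#' @param model A trained `gpvae`.
#' @param counts Count matrix, cells x genes.
#' @param conditions Per-cell condition labels known to the model.
#' @param group Factor with exactly two levels; the first level is group a.
#' @param threshold Enrichment threshold on `|log K|` (default 2.3).
#' @param n_pairs,method,n_draws,clip,seed Passed to [gp_bayes_factor()].
#' @param direction_method `"sum"` or `"counts"`; see [gp_direction()].
#' @param directed Test directed scores (latent scores multiplied by the
#'   program direction) instead of raw scores (default `FALSE`).
#' @return A data frame of class `gp_test` with columns `program`,
#'   `log_bayes_factor`, `p_h0`, `direction`, `enriched`, `n_cells_a`,
#'   `n_cells_b`, sorted by decreasing `|log K|`.
#' @export
rank_gps <- function(model, counts, conditions = NULL, group,
                     threshold = 2.3, n_pairs = 10000L,
                     method = c("closed_form", "sampling"), n_draws = 500L,
                     clip = 1e-7, seed = 1L,
                     direction_method = c("sum", "counts"), directed = FALSE) {
  method <- match.arg(method)
  direction_method <- match.arg(direction_method)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  post <- posterior_params(model, counts, conditions)
  a <- group == levels(group)[1L]
  b <- !a
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  active <- setdiff(model$program_names, deactivated_gps(model))
  dirs <- vapply(active, function(p) {
    gp_direction(model$dec$W[, p], direction_method)
  }, numeric(1))
  res <- lapply(active, function(p) {
    mu <- post$mu[, p]
    s2 <- post$sigma2[, p]
    if (directed) mu <- mu * dirs[[p]]
    bf <- gp_bayes_factor(mu[a], s2[a], mu[b], s2[b], n_pairs = n_pairs,
                          method = method, n_draws = n_draws, clip = clip,
                          seed = seed)
    data.frame(program = p, log_bayes_factor = bf$log_bayes_factor,
               p_h0 = bf$p_h0, direction = dirs[[p]],
               enriched = abs(bf$log_bayes_factor) >= threshold,
               n_cells_a = sum(a), n_cells_b = sum(b))
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$log_bayes_factor)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gp_test", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.gp_test <- function(x, ...) {
  cat("Differential gene-program test (", sum(x$enriched), " of ", nrow(x),
      " programs enriched at |log K| >= ", attr(x, "threshold"), ")\n",
      sep = "")
  print.data.frame(utils::head(x, 15L), digits = 3)
  if (nrow(x) > 15L) cat("... and", nrow(x) - 15L, "more programs\n")
  invisible(x)
}

#' Gene importance within a program
#'
#' The importance of a gene for a program is the absolute value of its
#' decoder weight in the program's column: the linear decoder makes the
#' reconstruction of genes with larger absolute weights respond more to a
#' change in the program's latent score.
#'
#' @param model A trained `gpvae`.
#' @param program Program name or column index.
#' @return Data frame with `gene`, `weight` and `score = |weight|`, sorted by
#'   decreasing score; ties broken by gene name.
#' @export
gene_importance <- function(model, program) {
  w <- model$dec$W[, program]
  out <- data.frame(gene = model$gene_names, weight = w, score = abs(w))
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predominant regulation direction of a program
#'
#' Sign heuristic aligning a program's latent score with upregulation of its
#' genes: `"sum"` takes the sign of the summed column weights; `"counts"`
#' takes the sign of the majority weight sign. An exactly zero aggregate
#' returns `+1` by convention.
#'
#' @param w Numeric decoder column (or any weight vector).
#' @param method `"sum"` (default) or `"counts"`.
#' @return `+1` or `-1`.
#' @examples
#' gp_direction(c(1, 2, -0.5))             # +1
#' gp_direction(c(1, -2, -0.5), "counts")  # -1
#' @export
gp_direction <- function(w, method = c("sum", "counts")) {
  method <- match.arg(method)
  if (length(w) == 0L) stop("empty weight column")
  s <- switch(method, sum = sum(w), counts = sum(sign(w)))
  if (s < 0) -1 else 1
}

#' Sign-align latent scores with their program directions
#'
#' Multiplies each latent score column by its program's direction so that a
#' higher directed score always means predominant upregulation.
#'
#' @param Z Latent score matrix, cells x programs.
#' @param directions Vector of `+1`/`-1`, one per column.
#' @return Matrix of directed scores.
#' @export
directed_scores <- function(Z, directions) {
  if (length(directions) != ncol(Z)) {
    stop("directions must have one entry per latent dimension")
  }
  sweep(Z, 2L, directions, "*")
}

#' Normalized entropy of a score distribution
#'
#' Shannon entropy of the scores (normalized to a probability vector) divided
#' by the entropy of the uniform distribution of the same size. 0 means one
#' entry carries all weight; 1 means uniformly spread weights. Used to
#' quantify how concentrated a program's gene-importance scores are.
#'
#' @param scores Nonnegative vector with at least 2 entries and positive sum.
#' @return A number in `[0, 1]`.
#' @examples
#' normalized_entropy(c(1, 1, 1, 1))  # 1
#' normalized_entropy(c(1, 0, 0))     # 0
#' @export
normalized_entropy <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (any(scores < 0)) stop("scores must be nonnegative")
  tot <- sum(scores)
  if (tot <= 0) stop("scores sum to zero; entropy undefined")
  p <- scores / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(scores))
}
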