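test_that("pairwise exceedance probability matches symmetry, limits and sampling", {
  expect_equal(pairwise_h0_prob(1.3, 0.5, 1.3, 2), 0.5)
  expect_gt(pairwise_h0_prob(100, 1, 0, 1), 1 - 1e-12)
  expect_error(pairwise_h0_prob(0, -1, 0, 1))

  # strictly inside (0,1) and monotone in the mean difference
  ps <- pairwise_h0_prob(seq(-3, 3, by = 0.5), 1, 0, 1)
  expect_true(all(ps > 0 & ps < 1))
  expect_true(all(diff(ps) > 0))

  # Monte-Carlo oracle with 1e6 paired draws
  set.seed(14)
  mu1 <- 0.7; s1 <- 1.3; mu2 <- -0.2; s2 <- 0.6
  d <- stats::rnorm(1e6, mu1, sqrt(s1)) > stats::rnorm(1e6, mu2, sqrt(s2))
  se <- stats::sd(d) / sqrt(1e6)
  expect_lt(abs(pairwise_h0_prob(mu1, s1, mu2, s2) - mean(d)), 3 * se)
})

test_that("log-Bayes factors are antisymmetric and zero for identical groups", {
  set.seed(9)
  mu <- stats::rnorm(40); s2 <- stats::runif(40, 0.2, 2)
  same <- gp_bayes_factor(mu, s2, mu, s2, n_pairs = 2000, seed = 5)
  # identical cells in both groups under closed form: p = 0.5 exactly
  expect_equal(same$p_h0, 0.5)
  expect_equal(same$log_bayes_factor, 0)

  mu2 <- stats::rnorm(30, 1); s22 <- stats::runif(30, 0.2, 2)
  ab <- gp_bayes_factor(mu, s2, mu2, s22, n_pairs = 3000, seed = 7)
  ba <- gp_bayes_factor(mu2, s22, mu, s2, n_pairs = 3000, seed = 7)
  # same seed draws the same pairing, so the flip is exact
  expect_equal(ab$log_bayes_factor, -ba$log_bayes_factor, tolerance = 1e-12)
})

test_that("sampling estimator agrees with the closed form within binomial error", {
  set.seed(22)
  mu_a <- stats::rnorm(25, 0.5); s_a <- stats::runif(25, 0.3, 1.5)
  mu_b <- stats::rnorm(25); s_b <- stats::runif(25, 0.3, 1.5)
  cf <- gp_bayes_factor(mu_a, s_a, mu_b, s_b, n_pairs = 400, seed = 3)
  mc <- gp_bayes_factor(mu_a, s_a, mu_b, s_b, n_pairs = 400, seed = 3,
                        method = "sampling", n_draws = 500)
  se <- sqrt(cf$p_h0 * (1 - cf$p_h0) / (400 * 500))
  expect_lt(abs(cf$p_h0 - mc$p_h0), max(3 * se, 5e-3))
})

test_that("probability clipping keeps extreme Bayes factors finite", {
  bf <- gp_bayes_factor(rep(100, 5), rep(0.1, 5), rep(-100, 5), rep(0.1, 5),
                        n_pairs = 100, clip = 1e-7)
  expect_equal(bf$log_bayes_factor, log((1 - 1e-7) / 1e-7))
})

test_that("rank_gps excludes deactivated programs, sorts and flags enrichment", {
  fx <- tiny_model()
  m <- fx$model
  X <- fx$sim$counts; cc <- fx$sim$conditions
  set.seed(1)
  grp <- factor(sample(c("a", "b"), nrow(X), replace = TRUE))
  res <- rank_gps(m, X, cc, grp, n_pairs = 2000)
  expect_s3_class(res, "gp_test")
  expect_setequal(res$program,
                  setdiff(m$program_names, deactivated_gps(m)))
  expect_true(all(diff(abs(res$log_bayes_factor)) <= 1e-12))
  expect_true(all(res$n_cells_a == sum(grp == "a")))

  resInf <- rank_gps(m, X, cc, grp, threshold = Inf, n_pairs = 500)
  expect_false(any(resInf$enriched))
  expect_error(rank_gps(m, X, cc, factor(rep("a", nrow(X)))), "two levels")
})

test_that("gene importance ranks by absolute weight with lexicographic ties", {
  fx <- tiny_model()
  m <- fx$model
  m$gene_names <- paste0("g", seq_along(m$gene_names))
  m$dec$W[] <- 0
  m$dec$W[1:3, 1] <- c(0.5, -2, 0)
  gi <- gene_importance(m, 1)
  expect_equal(gi$gene[1:2], c("g2", "g1"))
  expect_equal(gi$score[1:2], c(2, 0.5))
  # ties (all the zeros) are ordered by gene name
  zeros <- gi$gene[gi$score == 0]
  expect_equal(zeros, sort(zeros))
  # deactivated column: all-zero scores
  expect_true(all(gene_importance(m, 2)$score == 0))
})

test_that("program directions follow the sum/counts heuristics with +1 ties", {
  expect_equal(gp_direction(c(1, 2, -0.5), "sum"), 1)
  expect_equal(gp_direction(c(1, -2, -0.5), "counts"), -1)
  expect_equal(gp_direction(c(1, -1), "sum"), 1)      # documented tie-break
  expect_equal(gp_direction(c(0, 0), "counts"), 1)
  expect_error(gp_direction(numeric(0)), "empty")
})

test_that("directed scores flip columns and are involutive", {
  set.seed(2)
  Z <- matrix(stats::rnorm(12), 3)
  d <- c(1, -1, -1, 1)
  expect_equal(directed_scores(Z, rep(1, 4)), Z)
  expect_equal(directed_scores(directed_scores(Z, d), d), Z)
  expect_equal(directed_scores(Z, d), sweep(Z, 2, d, "*"))
  expect_error(directed_scores(Z, c(1, -1)), "one entry per")
})

test_that("normalized entropy spans [0, 1] with the hand-computed middle case", {
  expect_equal(normalized_entropy(rep(0.2, 7)), 1)
  expect_equal(normalized_entropy(c(5, 0, 0, 0)), 0)
  # (1/2, 1/4, 1/4): entropy 1.5 bits over log2(3)
  expect_equal(normalized_entropy(c(0.5, 0.25, 0.25)), 1.5 / log2(3),
               tolerance = 1e-12)
  expect_error(normalized_entropy(c(0, 0)), "zero")
  expect_error(normalized_entropy(5), "at least 2")
  expect_error(normalized_entropy(c(-1, 2)), "nonnegative")
})

test_that("null group labels rarely reach the enrichment threshold", {
  fx <- tiny_model()
  m <- fx$model
  X <- fx$sim$counts; cc <- fx$sim$conditions
  set.seed(33)
  n_enriched <- 0L; n_total <- 0L
  for (rep in 1:20) {
    grp <- factor(sample(c("a", "b"), nrow(X), replace = TRUE))
    res <- rank_gps(m, X, cc, grp, n_pairs = 1500, seed = rep)
    n_enriched <- n_enriched + sum(res$enriched)
    n_total <- n_total + nrow(res)
  }
  expect_lte(n_enriched / n_total, 0.05)
})
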