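test_that("closed-form proximal operators match their defining examples", {
  expect_equal(prox_l1(c(2, -2, 0.3), 0.5), c(1.5, -1.5, 0))
  expect_equal(prox_l1(c(-1, 0, 2), 0), c(-1, 0, 2))
  expect_equal(prox_group_lasso(c(3, 4), 1), c(2.4, 3.2))
  expect_equal(prox_group_lasso(c(0.1, 0.1), 1), c(0, 0))
  expect_equal(prox_masked_l1(c(2, 2), c(0, 1), 0.5), c(2, 1.5))
  expect_equal(prox_masked_l1(c(2, -2), c(0, 0), 5), c(2, -2))
  expect_error(prox_masked_l1(c(1, 2), c(0, 1, 1), 0.5), "length")
  v <- c(-0.3, 1.7, 0.2)
  expect_equal(prox_gp_column(v, c(1, 0, 1), 0, 0), v)
})

test_that("each closed form equals the numerical argmin of its objective", {
  set.seed(42)
  for (rep in 1:60) {
    d <- sample(1:50, 1)
    v <- stats::rnorm(d, sd = sample(c(0.1, 1, 10), 1))
    t1 <- 10^stats::runif(1, -3, 0.5)
    t2 <- 10^stats::runif(1, -3, 0.5)
    m <- sample(0:1, d, replace = TRUE)
    expect_lt(max(abs(prox_l1(v, t1) - numerical_prox(v, gamma1 = t1))), 1e-6)
    expect_lt(max(abs(prox_group_lasso(v, t1) -
                        numerical_prox(v, alpha2 = t1))), 1e-6)
    expect_lt(max(abs(prox_masked_l1(v, m, t1) -
                        numerical_prox(v, gamma1 = t1, m = m))), 1e-6)
    # composition equals the joint prox (masked L1 then group shrinkage)
    expect_lt(max(abs(prox_gp_column(v, m, t1, t2) -
                        numerical_prox(v, alpha2 = t1, gamma1 = t2, m = m))),
              1e-6)
  }
})

test_that("proximal operators are firmly non-expansive", {
  set.seed(7)
  for (rep in 1:50) {
    d <- sample(1:20, 1)
    u <- stats::rnorm(d); v <- stats::rnorm(d)
    t1 <- 10^stats::runif(1, -2, 1)
    m <- sample(0:1, d, replace = TRUE)
    for (f in list(function(x) prox_l1(x, t1),
                   function(x) prox_group_lasso(x, t1),
                   function(x) prox_gp_column(x, m, t1, t1 / 2))) {
      expect_lte(sqrt(sum((f(u) - f(v))^2)), sqrt(sum((u - v)^2)) + 1e-12)
    }
  }
})

test_that("apply_decoder_prox dispatches per column role and respects freezing", {
  set.seed(3)
  G <- 5
  W <- matrix(stats::rnorm(G * 5), G)
  M <- cbind(c(0, 0, 1, 1, 1), c(0, 1, 1, 0, 1), rep(1, G), c(0, 0, 0, 1, 1),
             c(0, 1, 0, 1, 0))
  roles <- c("hard", "soft", "new_unconstrained", "new_constrained_soft",
             "new_constrained_hard")
  cfg <- prox_config(alpha = 0.3, gamma = 0.2, gamma_ext = 0.1, alpha_l1 = 0.15)
  eta <- 0.5
  out <- apply_decoder_prox(W, M, roles, eta, cfg)

  h <- W[, 1]; h[M[, 1] != 0] <- 0
  expect_equal(out[, 1], prox_group_lasso(h, eta * cfg$alpha))
  expect_equal(out[, 2], prox_gp_column(W[, 2], M[, 2], eta * cfg$alpha,
                                        eta * cfg$gamma))
  expect_equal(out[, 3], prox_l1(W[, 3], eta * cfg$gamma_ext))
  expect_equal(out[, 4], prox_masked_l1(W[, 4], M[, 4], eta * cfg$alpha_l1))
  ch <- W[, 5]; ch[M[, 5] != 0] <- 0
  expect_equal(out[, 5], ch)

  # zero strengths: only mask enforcement remains
  z <- apply_decoder_prox(W, M, roles, eta,
                          prox_config(alpha = 0, gamma = 0, gamma_ext = 0,
                                      alpha_l1 = 0))
  expect_equal(z[, 2], W[, 2])
  expect_equal(z[, 3], W[, 3])
  expect_true(all(z[M[, 1] != 0, 1] == 0))

  # frozen columns pass through untouched
  fr <- apply_decoder_prox(W, M, roles, eta, cfg, frozen_cols = c(1, 3))
  expect_identical(fr[, 1], W[, 1])
  expect_identical(fr[, 3], W[, 3])
  expect_equal(fr[, 2], out[, 2])

  expect_error(apply_decoder_prox(W, M, c(roles[-1], "bogus"), eta, cfg),
               "unknown column role")
})

test_that("soft_mask_penalty matches direct summation", {
  set.seed(9)
  W <- matrix(stats::rnorm(12), 4)
  M <- matrix(sample(0:1, 12, replace = TRUE), 4)
  expect_equal(soft_mask_penalty(W, M, 0.7), 0.7 * sum(abs(W * M)))
  expect_equal(soft_mask_penalty(W * 0, M, 0.7), 0)
  expect_equal(soft_mask_penalty(W, M * 0, 0.7), 0)
})
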