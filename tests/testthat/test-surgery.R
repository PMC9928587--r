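test_that("extension grows the model without disturbing reference cells", {
  fx <- tiny_model()
  m <- fx$model
  P0 <- length(m$program_names)
  ext <- extend_gpvae(m, new_conditions = "query1", n_new_unconstrained = 3,
                      seed = 2)
  expect_equal(length(ext$program_names), P0 + 3L)
  expect_equal(ncol(ext$dec$W), P0 + 3L)
  expect_equal(ncol(ext$enc$Wmu), P0 + 3L)
  expect_equal(ncol(ext$dec$L), nlevels(fx$sim$conditions) + 1L)
  expect_true(all(ext$dec$W[, P0 + 1:3] == 0))
  expect_true(all(ext$dec$L[, ncol(ext$dec$L)] == 0))
  expect_equal(ext$roles[P0 + 1:3], rep("new_unconstrained", 3))
  expect_equal(ext$hsic_new_idx, P0 + 1:3)

  # reference cells: old-program latent scores and reconstructions unchanged
  X <- fx$sim$counts[1:15, ]; cc <- fx$sim$conditions[1:15]
  lat0 <- latent_scores(m, X, cc)
  lat1 <- latent_scores(ext, X, cc)
  expect_equal(lat1[, 1:P0], lat0, tolerance = 1e-12)
  r0 <- predict(m, X, cc, type = "response")
  r1 <- predict(ext, X, cc, type = "response")
  expect_equal(r1, r0, tolerance = 1e-12)

  # zero new nodes, one new condition: decode of reference cells unchanged
  ext0 <- extend_gpvae(m, new_conditions = "query1", n_new_unconstrained = 0)
  expect_equal(predict(ext0, X, cc, type = "response"), r0, tolerance = 1e-12)

  expect_error(extend_gpvae(m, new_conditions = levels(fx$sim$conditions)[1]),
               "collides")
  expect_error(extend_gpvae(ext), "already been extended")
})

test_that("new constrained program columns carry their mask and role", {
  fx <- tiny_model()
  m <- fx$model
  nc <- build_gp_mask(
    structure(list(newprog = m$gene_names[1:8]),
              class = "gene_set_collection"),
    m$gene_names, min_genes = 5, soft = TRUE)
  ext <- extend_gpvae(m, new_conditions = "q", new_constrained = nc,
                      n_new_unconstrained = 2)
  P0 <- length(m$program_names)
  expect_equal(ext$program_names[P0 + 1L], "newprog")
  expect_equal(ext$roles[P0 + 1L], "new_constrained_soft")
  expect_equal(unname(ext$mask$B[1:8, P0 + 1L]), rep(1, 8))
  # HSIC applies to the unconstrained nodes only
  expect_equal(ext$hsic_new_idx, P0 + 1L + 1:2)
})

test_that("serialization commutes with extension", {
  fx <- tiny_model()
  m <- fx$model
  tf <- withr::local_tempfile(fileext = ".rds")
  save_gpvae(m, tf)
  e1 <- extend_gpvae(load_gpvae(tf), new_conditions = "q",
                     n_new_unconstrained = 2, seed = 9)
  e2 <- extend_gpvae(m, new_conditions = "q", n_new_unconstrained = 2,
                     seed = 9)
  expect_identical(gpvae:::model_checksum(e1), gpvae:::model_checksum(e2))
})

test_that("query mapping trains only the extension partition", {
  fx <- tiny_model()
  m <- fx$model
  qsim <- simulate_query_counts(fx$sim, n_cells = 200, condition = "query1",
                                seed = 8)
  ext <- extend_gpvae(m, new_conditions = "query1", n_new_unconstrained = 2,
                      seed = 4)

  # zero learning rates: mapped model identical to the extended model
  m0 <- map_query(ext, qsim$counts, qsim$conditions, epochs = 1,
                  lr = 0, lr_decoder = 0, early_stopping = FALSE, seed = 1)
  expect_identical(m0$dec, ext$dec)
  expect_identical(m0$enc, ext$enc)

  before <- frozen_checksum(ext)
  mq <- map_query(ext, qsim$counts, qsim$conditions, epochs = 8,
                  batch_size = 64, early_stopping = FALSE, seed = 1)
  expect_identical(frozen_checksum(mq), before)

  # reference cells keep their old-program latent scores exactly
  X <- fx$sim$counts[1:10, ]; cc <- fx$sim$conditions[1:10]
  P0 <- length(m$program_names)
  expect_equal(latent_scores(mq, X, cc)[, 1:P0], latent_scores(m, X, cc),
               tolerance = 1e-12)

  # query must not reuse reference condition labels
  expect_error(map_query(ext, fx$sim$counts[1:5, ], fx$sim$conditions[1:5]),
               "reference condition")
  expect_error(map_query(m, qsim$counts, qsim$conditions), "extend_gpvae")
})

test_that("HSIC regularization lowers correlation of new nodes with old ones", {
  fx <- tiny_model()
  qsim <- simulate_query_counts(fx$sim, n_cells = 250, condition = "query1",
                                planted_query_program = list(n_genes = 8,
                                                             shift = 2,
                                                             fraction = 0.5),
                                seed = 13)
  P0 <- length(fx$model$program_names)
  cors <- sapply(c(0, 20), function(nu) {
    out <- numeric(3)
    for (s in 1:3) {
      ext <- extend_gpvae(fx$model, new_conditions = "query1",
                          n_new_unconstrained = 2, seed = s)
      mq <- map_query(ext, qsim$counts, qsim$conditions, epochs = 25,
                      batch_size = 64, nu = nu, early_stopping = FALSE,
                      seed = s)
      lat <- latent_scores(mq, qsim$counts, qsim$conditions)
      out[s] <- mean(abs(stats::cor(lat[, P0 + 1:2], lat[, 1:P0])))
    }
    mean(out)
  })
  expect_lt(cors[2], cors[1])
})
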