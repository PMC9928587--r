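test_that("simulation is deterministic, integer-valued and structured as declared", {
  s1 <- simulate_gp_counts(n_cells = 100, n_genes = 120, n_programs_active = 3,
                           n_programs_null = 2, genes_per_program = 10,
                           seed = 7)
  s2 <- simulate_gp_counts(n_cells = 100, n_genes = 120, n_programs_active = 3,
                           n_programs_null = 2, genes_per_program = 10,
                           seed = 7)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == round(s1$counts)))
  expect_length(s1$gene_sets, 5L)
  expect_length(s1$truth$active_programs, 3L)
  # program gene blocks are disjoint
  all_genes <- unlist(s1$gene_sets)
  expect_false(anyDuplicated(all_genes) > 0)
  # null programs have zero true weight columns, active ones do not
  expect_true(all(s1$truth$W_true[, s1$truth$null_programs] == 0))
  expect_true(all(colSums(abs(s1$truth$W_true[, s1$truth$active_programs])) > 0))

  expect_error(simulate_gp_counts(n_genes = 50, n_programs_active = 5,
                                  n_programs_null = 5, genes_per_program = 20),
               "infeasible")
})

test_that("zero effect and zero batch shift degenerate as expected", {
  s0 <- simulate_gp_counts(n_cells = 2000, n_genes = 60, n_programs_active = 2,
                           n_programs_null = 1, genes_per_program = 10,
                           effect_sd = 0, batch_shift_sd = 0, seed = 3)
  expect_true(all(s0$truth$W_true == 0))
  # with no batch shift, condition-wise mean expression agrees within 3 SE
  g <- s0$counts[, 1:20]
  a <- s0$conditions == levels(s0$conditions)[1]
  diff_ <- colMeans(g[a, ]) - colMeans(g[!a, ])
  se <- sqrt(apply(g[a, ], 2, stats::var) / sum(a) +
               apply(g[!a, ], 2, stats::var) / sum(!a))
  expect_true(all(abs(diff_) < 4 * se))
})

test_that("planted effects are recorded in the truth record", {
  s <- simulate_gp_counts(n_cells = 150, n_genes = 150, n_programs_active = 2,
                          n_programs_null = 2, genes_per_program = 10,
                          group_effect = list(program = 1, shift = 2),
                          planted_query_program = list(n_genes = 10, shift = 2,
                                                       fraction = 0.4),
                          seed = 5)
  expect_s3_class(s$truth$group, "factor")
  expect_equal(s$truth$group_program, "prog_active_01")
  expect_length(s$truth$query_program_genes, 10L)
  expect_type(s$truth$perturbed, "logical")
  # query-program genes belong to no simulated gene set
  expect_length(intersect(s$truth$query_program_genes, unlist(s$gene_sets)), 0L)
})

test_that("query simulation reuses the reference truth on the same gene axis", {
  ref <- tiny_sim()
  q <- simulate_query_counts(ref, n_cells = 80, condition = "queryX",
                             planted_query_program = list(n_genes = 6,
                                                          shift = 2,
                                                          fraction = 0.5),
                             seed = 4)
  expect_identical(q$gene_names, ref$gene_names)
  expect_equal(levels(q$conditions), "queryX")
  expect_length(intersect(q$truth$query_program_genes, unlist(ref$gene_sets)),
                0L)
  q2 <- simulate_query_counts(ref, n_cells = 80, condition = "queryX",
                              planted_query_program = list(n_genes = 6,
                                                           shift = 2,
                                                           fraction = 0.5),
                              seed = 4)
  expect_identical(q$counts, q2$counts)
})

test_that("fixtures round-trip exactly through Matrix Market, GMT and JSON", {
  s <- simulate_gp_counts(n_cells = 60, n_genes = 100, n_programs_active = 2,
                          n_programs_null = 1, genes_per_program = 8, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_fixture(s, dir)
  expect_true(all(file.exists(paths)))

  ds <- read_dataset(paths[["counts"]], paths[["cells"]], paths[["genes"]])
  expect_equal(unname(as.matrix(ds$counts)), unname(s$counts))
  expect_equal(as.character(ds$conditions), as.character(s$conditions))
  expect_equal(ds$gene_names, s$gene_names)

  back <- read_gmt(paths[["sets"]])
  expect_equal(unclass(back), unclass(s$gene_sets), ignore_attr = TRUE)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$active_programs, s$truth$active_programs)

  # orientation flag transposes on load
  tm <- file.path(dir, "t.mtx")
  Matrix::writeMM(Matrix::t(Matrix::Matrix(s$counts, sparse = TRUE)), tm)
  ds2 <- read_dataset(tm, paths[["cells"]], paths[["genes"]],
                      orientation = "genes_by_cells")
  expect_equal(unname(as.matrix(ds2$counts)), unname(s$counts))

  expect_error(read_dataset(paths[["counts"]], paths[["cells"]],
                            paths[["genes"]], condition_column = "nope"),
               "not found")
})

test_that("non-integer matrices are rejected with advice about raw counts", {
  dir <- withr::local_tempdir()
  M <- Matrix::Matrix(c(0, 1.5, 2, 0), 2, 2, sparse = TRUE)
  Matrix::writeMM(M, file.path(dir, "bad.mtx"))
  utils::write.table(data.frame(cell_id = c("c1", "c2"),
                                condition = c("x", "x")),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(gene = c("g1", "g2")),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(file.path(dir, "bad.mtx"),
                            file.path(dir, "cells.tsv"),
                            file.path(dir, "genes.tsv")),
               "raw integer")
})

test_that("model archives round-trip bit-exactly and refuse foreign files", {
  fx <- tiny_model()
  tf <- withr::local_tempfile(fileext = ".rds")
  save_gpvae(fx$model, tf)
  back <- load_gpvae(tf)
  expect_identical(gpvae:::model_checksum(back),
                   gpvae:::model_checksum(fx$model))
  X <- fx$sim$counts[1:10, ]; cc <- fx$sim$conditions[1:10]
  expect_identical(latent_scores(back, X, cc), latent_scores(fx$model, X, cc))

  saveRDS(list(a = 1), tf)
  expect_error(load_gpvae(tf), "not a gpvae model archive")
  saveRDS(list(format = "gpvae_model", version = 99L, model = 1), tf)
  expect_error(load_gpvae(tf), "version")
})
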