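#' Simulate negative-binomial counts with planted gene-program structure
#'
#' Generates a synthetic single-cell count dataset from the model's own
#' generative family: latent scores `Z ~ N(0, I)`; a sparse true weight
#' matrix in which each *active* program assigns Gaussian weights
#' (`sd = effect_sd`) to its block of member genes while *null* programs have
#' all-zero columns; per-condition batch offsets with `sd = batch_shift_sd`;
#' means `softmax(Z W' + C L') * S` with log-normal library sizes; and counts
#' drawn NB with common dispersion. Gene blocks are disjoint across programs.
#' The emitted gene-set collection covers active and null programs alike, so
#' a fit must discover which programs carry signal. Optional extras plant a
#' group effect (a latent shift of one program in half the cells, for testing
#' differential-program detection) or a query-only program (a block of
#' otherwise unused genes activated in a fraction of cells, for testing
#' query-time discovery of new programs).
#'
#' @param n_cells,n_genes Dataset size (defaults 2000 x 500).
#' @param n_programs_active Programs with real signal (default 10).
#' @param n_programs_null Decoy programs with no signal (default 10).
#' @param n_conditions Number of batches (default 2).
#' @param genes_per_program Genes per program block (default 20).
#' @param effect_sd SD of the true member weights of active programs
#'   (default 1; roughly e-fold expression swings per latent SD).
#' @param batch_shift_sd SD of the per-gene batch offsets (default 0.1).
#' @param dispersion NB dispersion `theta` (default 5).
#' @param library_meanlog,library_sdlog Log-normal library-size parameters
#'   (defaults `log(5000)` and 0.3).
#' @param group_effect Optional `list(program =, shift =)`: cells of group
#'   "a" (a random half) get `shift` added to that active program's latent
#'   score.
#' @param planted_query_program Optional `list(n_genes =, shift =, fraction =)`:
#'   a new program over previously unused genes is active (latent score
#'   `shift`) in a random `fraction` of cells ("perturbed" cells in the truth
#'   record).
#' @param misspecify Add log-normal noise (sd 0.2) to the NB means, breaking
#'   the model family for robustness checks (default `FALSE`).
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return A list of class `gp_sim`: integer `counts` (cells x genes with
#'   dimnames), `conditions` factor, `gene_names`, `cell_ids`, `gene_sets`
#'   (a `gene_set_collection` over all programs), and `truth` (active/null
#'   program names, true weights, `group` factor and `perturbed` flags when
#'   planted, query-program genes).
#' @export
simulate_gp_counts <- function(n_cells = 2000L, n_genes = 500L,
                               n_programs_active = 10L, n_programs_null = 10L,
                               n_conditions = 2L, genes_per_program = 20L,
                               effect_sd = 1, batch_shift_sd = 0.1,
                               dispersion = 5, library_meanlog = log(5000),
                               library_sdlog = 0.3, group_effect = NULL,
                               planted_query_program = NULL,
                               misspecify = FALSE, seed = 1L) {
  stopifnot(n_cells > 0, n_genes > 0, n_programs_active >= 0,
            n_programs_null >= 0, n_conditions >= 1, genes_per_program > 0,
            effect_sd >= 0, batch_shift_sd >= 0, dispersion > 0)
  n_prog <- n_programs_active + n_programs_null
  need <- n_prog * genes_per_program +
    if (!is.null(planted_query_program)) planted_query_program$n_genes else 0L
  if (need > n_genes) {
    stop("infeasible gene allocation: ", need, " program genes requested but ",
         "only ", n_genes, " genes available")
  }
  set.seed(seed)
  gene_names <- sprintf("g%04d", seq_len(n_genes))
  cell_ids <- sprintf("c%05d", seq_len(n_cells))
  pool <- sample(gene_names)            # shuffled disjoint allocation
  blocks <- split(pool[seq_len(n_prog * genes_per_program)],
                  rep(seq_len(n_prog), each = genes_per_program))
  prog_names <- c(sprintf("prog_active_%02d", seq_len(n_programs_active)),
                  sprintf("prog_null_%02d", seq_len(n_programs_null)))
  names(blocks) <- prog_names
  active <- prog_names[seq_len(n_programs_active)]

  W <- matrix(0, n_genes, n_prog, dimnames = list(gene_names, prog_names))
  for (p in active) {
    W[blocks[[p]], p] <- stats::rnorm(genes_per_program, sd = effect_sd)
  }
  cond <- factor(sample(sprintf("batch%d", seq_len(n_conditions)), n_cells,
                        replace = TRUE))
  L <- matrix(stats::rnorm(n_genes * n_conditions, sd = batch_shift_sd),
              n_genes, n_conditions,
              dimnames = list(gene_names, levels(cond)))

  Z <- matrix(stats::rnorm(n_cells * n_prog), n_cells, n_prog)
  truth <- list(active_programs = active,
                null_programs = setdiff(prog_names, active),
                W_true = W, group = NULL, perturbed = NULL,
                query_program_genes = NULL)
  if (!is.null(group_effect)) {
    grp <- factor(sample(c("a", "b"), n_cells, replace = TRUE))
    j <- group_effect$program
    if (is.character(j)) j <- match(j, prog_names)
    Z[grp == "a", j] <- Z[grp == "a", j] + group_effect$shift
    truth$group <- grp
    truth$group_program <- prog_names[j]
  }
  H <- tcrossprod(Z, W)
  if (!is.null(planted_query_program)) {
    qg <- pool[n_prog * genes_per_program + seq_len(planted_query_program$n_genes)]
    wq <- stats::rnorm(planted_query_program$n_genes, sd = effect_sd)
    pert <- stats::runif(n_cells) < planted_query_program$fraction
    zq <- ifelse(pert, planted_query_program$shift, 0)
    H[, ] <- H + outer(zq, {
      v <- numeric(n_genes); v[match(qg, gene_names)] <- wq; v
    })
    truth$perturbed <- pert
    truth$query_program_genes <- qg
    truth$query_program_weights <- stats::setNames(wq, qg)
  }
  H <- H + .one_hot(cond) %*% t(L)
  E <- exp(H - apply(H, 1L, max))
  P <- E / rowSums(E)
  S <- stats::rlnorm(n_cells, library_meanlog, library_sdlog)
  mu <- P * S
  if (misspecify) mu <- mu * stats::rlnorm(length(mu), 0, 0.2)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, size = dispersion,
                                  mu = as.vector(mu)),
                   n_cells, n_genes, dimnames = list(cell_ids, gene_names))

  sets <- structure(blocks, class = "gene_set_collection")
  structure(
    list(counts = counts, conditions = cond, gene_names = gene_names,
         cell_ids = cell_ids, gene_sets = sets, truth = truth,
         params = list(n_cells = n_cells, n_genes = n_genes,
                       n_programs_active = n_programs_active,
                       n_programs_null = n_programs_null,
                       genes_per_program = genes_per_program,
                       effect_sd = effect_sd, batch_shift_sd = batch_shift_sd,
                       dispersion = dispersion, seed = seed)),
    class = "gp_sim"
  )
}

#' @export
print.gp_sim <- function(x, ...) {
  cat("Simulated gene-program dataset: ", nrow(x$counts), " cells x ",
      ncol(x$counts), " genes, ", length(x$gene_sets), " programs (",
      length(x$truth$active_programs), " active), ",
      nlevels(x$conditions), " conditions\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the exact formats the command-line interface consumes: Matrix Market
#' counts (`counts.mtx`, cells x genes), cell metadata TSV (`cells.tsv` with
#' `cell_id`, `condition` and any planted truth columns), gene names TSV
#' (`genes.tsv`), the gene sets as GMT (`gene_sets.gmt`) and the truth record
#' as JSON (`truth.json`).
#'
#' @param sim A `gp_sim` from [simulate_gp_counts()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "gp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.mtx"),
             cells = file.path(dir, "cells.tsv"),
             genes = file.path(dir, "genes.tsv"),
             sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  Matrix::writeMM(methods::as(Matrix::Matrix(sim$counts, sparse = TRUE),
                              "generalMatrix"), paths[["counts"]])
  meta <- data.frame(cell_id = sim$cell_ids,
                     condition = as.character(sim$conditions))
  if (!is.null(sim$truth$group)) meta$group <- as.character(sim$truth$group)
  if (!is.null(sim$truth$perturbed)) meta$perturbed <- sim$truth$perturbed
  utils::write.table(meta, paths[["cells"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene = sim$gene_names), paths[["genes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, paths[["sets"]])
  truth <- sim$truth
  truth$W_true <- NULL                 # matrices do not belong in the record
  truth$group <- if (!is.null(truth$group)) as.character(truth$group)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}

#' Simulate query cells from an existing simulation's generative truth
#'
#' Draws a new batch of cells from the same true weight matrix and program
#' structure as a reference simulation, under one or more new condition
#' labels, optionally planting a query-only program: a block of genes unused
#' by any reference program, activated (latent score `shift`) in a random
#' `fraction` of the query cells. This is the surgery test bed: the reference
#' model has never seen the new conditions or the planted program.
#'
#' @param ref_sim A `gp_sim` from [simulate_gp_counts()].
#' @param n_cells Number of query cells (default 1000).
#' @param condition Single new condition label (default `"query1"`).
#' @param planted_query_program Optional
#'   `list(n_genes =, shift =, fraction =)` as in [simulate_gp_counts()];
#'   genes are taken from the reference's unassigned pool.
#' @param batch_shift_sd SD of the fresh per-gene batch offset of the query
#'   condition (default, the reference's value).
#' @param seed Integer seed.
#' @return A `gp_sim` over the same gene axis, with `truth$perturbed` flags
#'   and `truth$query_program_genes` when a program is planted.
#' @export
simulate_query_counts <- function(ref_sim, n_cells = 1000L,
                                  condition = "query1",
                                  planted_query_program = NULL,
                                  batch_shift_sd = ref_sim$params$batch_shift_sd,
                                  seed = 2L) {
  stopifnot(inherits(ref_sim, "gp_sim"))
  set.seed(seed)
  W <- ref_sim$truth$W_true
  gene_names <- ref_sim$gene_names
  n_genes <- length(gene_names)
  n_prog <- ncol(W)
  cell_ids <- sprintf("q%05d", seq_len(n_cells))
  Z <- matrix(stats::rnorm(n_cells * n_prog), n_cells, n_prog)
  H <- tcrossprod(Z, W)
  truth <- list(active_programs = ref_sim$truth$active_programs,
                null_programs = ref_sim$truth$null_programs,
                perturbed = NULL, query_program_genes = NULL)
  if (!is.null(planted_query_program)) {
    used <- unlist(ref_sim$gene_sets, use.names = FALSE)
    free <- setdiff(gene_names, used)
    if (length(free) < planted_query_program$n_genes) {
      stop("not enough unassigned genes for the planted query program")
    }
    qg <- sample(free, planted_query_program$n_genes)
    wq <- stats::rnorm(planted_query_program$n_genes,
                       sd = ref_sim$params$effect_sd)
    pert <- stats::runif(n_cells) < planted_query_program$fraction
    zq <- ifelse(pert, planted_query_program$shift, 0)
    v <- numeric(n_genes); v[match(qg, gene_names)] <- wq
    H <- H + outer(zq, v)
    truth$perturbed <- pert
    truth$query_program_genes <- qg
    truth$query_program_weights <- stats::setNames(wq, qg)
  }
  Lq <- stats::rnorm(n_genes, sd = batch_shift_sd)
  H <- H + matrix(Lq, n_cells, n_genes, byrow = TRUE)
  E <- exp(H - apply(H, 1L, max))
  P <- E / rowSums(E)
  S <- stats::rlnorm(n_cells, log(mean(rowSums(ref_sim$counts))), 0.3)
  counts <- matrix(stats::rnbinom(n_cells * n_genes,
                                  size = ref_sim$params$dispersion,
                                  mu = as.vector(P * S)),
                   n_cells, n_genes, dimnames = list(cell_ids, gene_names))
  structure(
    list(counts = counts,
         conditions = factor(rep(condition, n_cells)),
         gene_names = gene_names, cell_ids = cell_ids,
         gene_sets = ref_sim$gene_sets, truth = truth,
         params = ref_sim$params),
    class = "gp_sim"
  )
}
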