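#' Read an expression dataset from Matrix Market plus TSV metadata
#'
#' Loads a sparse count matrix together with cell metadata and gene names,
#' validating that entries are nonnegative integers (the negative-binomial
#' likelihood requires raw counts; normalized matrices are rejected).
#'
#' @param mtx_path Matrix Market file of counts.
#' @param cells_tsv TSV with one row per cell; must contain
#'   `condition_column`.
#' @param genes_tsv TSV with one row per gene; first column holds the gene
#'   names.
#' @param condition_column Name of the condition/batch column in `cells_tsv`
#'   (default `"condition"`).
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`, in
#'   which case the matrix is transposed on load.
#' @return A list of class `gp_dataset`: sparse `counts` (cells x genes),
#'   `cell_ids`, `gene_names`, `conditions` factor and the full `cell_meta`
#'   data frame.
#' @export
read_dataset <- function(mtx_path, cells_tsv, genes_tsv,
                         condition_column = "condition",
                         orientation = c("cells_by_genes", "genes_by_cells")) {
  orientation <- match.arg(orientation)
  counts <- Matrix::readMM(mtx_path)
  if (orientation == "genes_by_cells") counts <- Matrix::t(counts)
  meta <- utils::read.delim(cells_tsv, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_tsv, stringsAsFactors = FALSE)[[1L]]
  if (nrow(counts) != nrow(meta)) {
    stop("count matrix has ", nrow(counts), " cells but ", cells_tsv,
         " has ", nrow(meta), " rows (check the orientation flag)")
  }
  if (ncol(counts) != length(genes)) {
    stop("count matrix has ", ncol(counts), " genes but ", genes_tsv,
         " has ", length(genes))
  }
  if (!condition_column %in% names(meta)) {
    stop("condition column '", condition_column, "' not found in ", cells_tsv)
  }
  v <- counts@x
  if (any(v < 0) || any(abs(v - round(v)) > 1e-8)) {
    stop("matrix contains negative or non-integer entries; ",
         "raw integer counts are required for the NB likelihood")
  }
  cell_ids <- if ("cell_id" %in% names(meta)) meta$cell_id else
    sprintf("cell%05d", seq_len(nrow(meta)))
  dimnames(counts) <- list(cell_ids, genes)
  structure(
    list(counts = counts, cell_ids = cell_ids, gene_names = genes,
         conditions = factor(meta[[condition_column]]), cell_meta = meta),
    class = "gp_dataset"
  )
}

#' @export
print.gp_dataset <- function(x, ...) {
  cat("Expression dataset: ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes, conditions: ",
      paste(levels(x$conditions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.GPVAE_ARCHIVE_VERSION <- 1L

#' Save / load a model archive
#'
#' `save_gpvae()` writes the complete model state — decoder weights, encoder
#' weights, dispersions, program mask, configuration and training report — to
#' a single versioned archive; `load_gpvae()` restores it bit-exactly.
#' Archives written by an incompatible package version are refused.
#'
#' @param model A `gpvae` object.
#' @param path Archive path (conventionally `.rds`).
#' @return `save_gpvae()` returns `path` invisibly; `load_gpvae()` returns
#'   the model.
#' @export
save_gpvae <- function(model, path) {
  stopifnot(inherits(model, "gpvae"))
  saveRDS(list(format = "gpvae_model", version = .GPVAE_ARCHIVE_VERSION,
               package_version = as.character(utils::packageVersion("gpvae")),
               model = model),
          path, version = 3L)
  invisible(path)
}

#' @rdname save_gpvae
#' @export
load_gpvae <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "gpvae_model")) {
    stop("'", path, "' is not a gpvae model archive")
  }
  if (!identical(obj$version, .GPVAE_ARCHIVE_VERSION)) {
    stop("archive version ", obj$version, " is not supported by this ",
         "package build (expected ", .GPVAE_ARCHIVE_VERSION, ")")
  }
  obj$model
}

# md5 of a model's full serialized state (round-trip and freezing checks)
model_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model, f, version = 3L)
  unname(tools::md5sum(f))
}
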