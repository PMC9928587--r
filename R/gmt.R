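#' Read gene sets from a GMT-style file
#'
#' Reads tab-delimited gene-set files. Two dialects are in circulation: the
#' classic GMT layout `name<TAB>description<TAB>gene1<TAB>gene2...` and a plain
#' layout where every field after the name is a gene. With `dialect = "auto"`
#' (default) the second field is treated as a description only when it does not
#' recur among the remaining fields of the line, so a gene list whose first
#' gene also appears later is never truncated; force a dialect when the
#' heuristic cannot decide for your files.
#'
#' @param path Path to a tab-delimited gene-set file.
#' @param dialect One of `"auto"`, `"gmt"` (second column is always a
#'   description) or `"plain"` (every field after the name is a gene).
#' @return A `gene_set_collection`: a named list of character vectors of gene
#'   symbols, de-duplicated, in file order.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines(c("SETA\tdesc\tG1\tG2", "SETB\tG3\tG4"), tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path, dialect = c("auto", "gmt", "plain")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2L) {
      stop("malformed gene-set line ", i, ": fewer than 2 tab-separated fields")
    }
    name <- fields[[1L]]
    rest <- fields[-1L]
    genes <- switch(dialect,
      plain = rest,
      gmt = rest[-1L],
      auto = if (length(rest) > 1L && !(rest[[1L]] %in% rest[-1L])) rest[-1L] else rest
    )
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0L) {
      stop("gene-set line ", i, " ('", name, "') contains no genes")
    }
    if (name %in% names(sets)) {
      stop("duplicate gene-set name '", name, "' at line ", i)
    }
    sets[[name]] <- genes
  }
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' Writes the classic GMT layout (name, description, genes...). The
#' description column is filled with the set name, which round-trips through
#' [read_gmt()] under every dialect.
#'
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection with", length(x), "sets\n")
  if (length(x) > 0L) {
    sizes <- lengths(x)
    cat("  set sizes: min", min(sizes), "/ median", stats::median(sizes),
        "/ max", max(sizes), "\n")
    show <- utils::head(names(x), 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Build the binary gene-program mask for a gene universe
#'
#' Intersects each gene set with `gene_names` (the gene axis of the expression
#' matrix), drops programs that retain fewer than `min_genes` (or more than
#' `max_genes`) members, and constructs the binary membership matrix `B`
#' (genes x programs, `B[i,j] = 1` iff gene i belongs to program j) together
#' with its complement `M = 1 - B` used as the soft-membership penalty mask.
#' Optionally appends fully unconstrained sparse program columns, for which the
#' `B` column is all-zero and the `M` column all-one so that every gene weight
#' is L1-penalized.
#'
#' @param sets A `gene_set_collection` from [read_gmt()] (or a named list of
#'   gene vectors).
#' @param gene_names Character vector of the dataset's gene symbols, in the
#'   column order of the count matrix. Must be non-empty and free of
#'   duplicates.
#' @param min_genes Minimum surviving members for a program to be retained
#'   (default 12).
#' @param max_genes Optional maximum; programs with more surviving members are
#'   dropped.
#' @param soft Logical; if `TRUE` the curated columns use soft membership
#'   (non-members allowed but L1-penalized), otherwise hard membership
#'   (non-member decoder weights pinned to exactly zero).
#' @param ignore_case Logical; match gene symbols case-insensitively. Default
#'   `FALSE` (exact matching).
#' @param n_unconstrained Number of extra unconstrained sparse program columns
#'   to append (default 0).
#' @return A `gp_mask` object: list with `program_names`, `gene_names`, binary
#'   matrices `B` and `M`, and per-column `membership` in
#'   `c("hard", "soft", "unconstrained")`. Genes that belong to no retained
#'   program are reported in attribute `"unannotated_genes"`.
#' @examples
#' sets <- structure(list(A = c("g1", "g2", "g3")), class = "gene_set_collection")
#' build_gp_mask(sets, c("g1", "g2", "g3", "g4"), min_genes = 2)
#' @export
build_gp_mask <- function(sets, gene_names, min_genes = 12L, max_genes = NULL,
                          soft = FALSE, ignore_case = FALSE,
                          n_unconstrained = 0L) {
  if (length(gene_names) == 0L) stop("gene_names must be non-empty")
  if (anyDuplicated(gene_names)) {
    stop("gene_names contains duplicates; de-duplicate the gene axis first")
  }
  key <- if (ignore_case) toupper(gene_names) else gene_names
  if (ignore_case && anyDuplicated(key)) {
    stop("gene_names collide under case-insensitive matching")
  }
  keep <- list()
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (ignore_case) g <- toupper(g)
    idx <- which(key %in% g)
    if (length(idx) < min_genes) next
    if (!is.null(max_genes) && length(idx) > max_genes) next
    keep[[nm]] <- idx
  }
  if (length(keep) == 0L && n_unconstrained == 0L) {
    stop("no gene program survives the size filter (min_genes = ", min_genes,
         "); consider lowering min_genes")
  }
  n_cur <- length(keep)
  prog <- names(keep)
  if (n_unconstrained > 0L) {
    prog <- c(prog, sprintf("unconstrained_%02d", seq_len(n_unconstrained)))
  }
  B <- matrix(0, nrow = length(gene_names), ncol = length(prog),
              dimnames = list(gene_names, prog))
  for (j in seq_len(n_cur)) B[keep[[j]], j] <- 1
  M <- 1 - B
  # unconstrained sparse columns: B all-zero (already), M all-one (already)
  membership <- c(rep(if (soft) "soft" else "hard", n_cur),
                  rep("unconstrained", n_unconstrained))
  out <- structure(
    list(program_names = prog, gene_names = gene_names, B = B, M = M,
         membership = membership),
    class = "gp_mask"
  )
  attr(out, "unannotated_genes") <- gene_names[rowSums(B) == 0]
  out
}

#' @export
print.gp_mask <- function(x, ...) {
  tab <- table(factor(x$membership, levels = c("hard", "soft", "unconstrained")))
  cat("Gene-program mask: ", length(x$gene_names), " genes x ",
      length(x$program_names), " programs\n", sep = "")
  cat("  membership:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  szs <- colSums(x$B)
  if (any(x$membership != "unconstrained")) {
    cs <- szs[x$membership != "unconstrained"]
    cat("  curated program sizes: min", min(cs), "/ max", max(cs), "\n")
  }
  cat("  genes in no program:", length(attr(x, "unannotated_genes")), "\n")
  invisible(x)
}
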