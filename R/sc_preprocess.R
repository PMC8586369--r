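#' Construct a single-cell expression container
#'
#' Holds one 10x channel: a sparse genes-by-cells UMI count matrix plus,
#' after [normalize_expression()], the TPM-like values. Counts keep the MTX
#' orientation (genes as rows); all user-facing summaries come back as
#' tibbles.
#'
#' @param counts Sparse or dense genes-by-cells matrix of non-negative
#'   integer UMI counts with rownames = gene symbols, colnames = cellular
#'   cDNA indexes.
#' @param channel_id Label for the 10x channel.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(counts, channel_id = "channel1") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    abort("counts need gene rownames and cell colnames")
  }
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) {
    abort("UMI counts must be non-negative integers")
  }
  structure(list(counts = counts, tpm = NULL, channel_id = channel_id,
                 log2 = FALSE,
                 prefilter_cellsums = Matrix::colSums(counts)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix [", x$channel_id, "]: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " cells",
      if (!is.null(x$tpm)) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Read one 10x channel from MatrixMarket + TSV files
#'
#' Expects the Cell Ranger-style triplet: `matrix.mtx` (genes x cells),
#' `genes.tsv` (gene ids/symbols, first column used), `barcodes.tsv`.
#'
#' @param dir Directory containing the triplet, or `NULL` if explicit paths
#'   are given.
#' @param mtx,genes,barcodes Explicit file paths overriding `dir`.
#' @param channel_id Channel label; defaults to the directory name.
#' @return An [expr_matrix()].
#' @export
read_mtx_channel <- function(dir = NULL, mtx = NULL, genes = NULL,
                             barcodes = NULL, channel_id = NULL) {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    genes <- genes %||% file.path(dir, "genes.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    channel_id <- channel_id %||% basename(normalizePath(dir))
  }
  m <- Matrix::readMM(mtx)
  g <- utils::read.table(genes, sep = "\t", header = FALSE,
                         colClasses = "character")
  b <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                         colClasses = "character")
  rownames(m) <- g[[ncol(g)]]  # symbol column (last) per cellranger layout
  colnames(m) <- b[[1]]
  expr_matrix(m, channel_id = channel_id %||% "channel1")
}

#' Write an expr_matrix as MTX + TSV (+ parameter sidecar)
#'
#' @param m An [expr_matrix()].
#' @param dir Output directory (created if needed).
#' @param normalized Write the TPM-like matrix (`norm.mtx`) as well.
#' @param params Optional named list recorded in `params.json`.
#' @return `dir`, invisibly.
#' @export
write_mtx_channel <- function(m, dir, normalized = !is.null(m$tpm),
                              params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  if (normalized && !is.null(m$tpm)) {
    Matrix::writeMM(m$tpm, file.path(dir, "norm.mtx"))
  }
  if (!is.null(params)) {
    jsonlite::write_json(params, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Identify mitochondrial genes
#'
#' @param m An [expr_matrix()].
#' @param mito_genes Explicit gene list; overrides the prefix rule.
#' @param mito_prefix Prefix identifying mitochondrial gene symbols
#'   (human annotation default `"MT-"`).
#' @return Character vector of mitochondrial gene symbols present in `m`.
#' @export
mito_gene_set <- function(m, mito_genes = NULL, mito_prefix = "MT-") {
  g <- rownames(m$counts)
  if (!is.null(mito_genes)) {
    bad <- setdiff(mito_genes, g)
    if (length(bad)) abort(paste0("mito genes absent from matrix: ",
                                  paste(head(bad, 5), collapse = ", ")))
    return(mito_genes)
  }
  g[startsWith(g, mito_prefix)]
}

#' Remove cells with a high mitochondrial UMI fraction
#'
#' Cells whose mitochondrial fraction (mito UMIs / total UMIs, computed on
#' the raw counts before any gene filtering) is strictly greater than
#' `max_frac` are excluded. A cell at exactly `max_frac` is retained. Cells
#' with zero total UMIs have an undefined fraction and are removed with a
#' warning.
#'
#' @inheritParams mito_gene_set
#' @param max_frac Maximum tolerated mitochondrial fraction; default 0.10.
#' @return The filtered [expr_matrix()]; per-channel before/after cell
#'   counts recorded in attribute `cell_filter`.
#' @export
filter_cells_by_mito <- function(m, mito_genes = NULL, max_frac = 0.10,
                                 mito_prefix = "MT-") {
  stopifnot(inherits(m, "expr_matrix"))
  mito <- mito_gene_set(m, mito_genes, mito_prefix)
  tot <- Matrix::colSums(m$counts)
  mito_umis <- if (length(mito)) {
    Matrix::colSums(m$counts[mito, , drop = FALSE])
  } else rep(0, ncol(m$counts))
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " cell(s) with zero UMIs removed ",
                "(mitochondrial fraction undefined)"))
  }
  frac <- ifelse(zero, Inf, mito_umis / tot)
  keep <- frac <= max_frac
  out <- m
  out$counts <- m$counts[, keep, drop = FALSE]
  out$prefilter_cellsums <- m$prefilter_cellsums[keep]
  attr(out, "cell_filter") <- list(before = ncol(m$counts),
                                   after = sum(keep), max_frac = max_frac)
  out
}

#' Keep genes expressed above threshold in enough cells
#'
#' A gene is retained iff the fraction of cells with strictly more than
#' `min_umi` UMIs is strictly greater than `min_cell_frac` (both
#' inequalities strict: a gene at exactly 2 UMIs everywhere, or present in
#' exactly 5.0% of cells, is removed).
#'
#' @param m An [expr_matrix()] (cell filter already applied).
#' @param min_umi UMI count a cell must exceed to count as expressing;
#'   default 2.
#' @param min_cell_frac Fraction of cells that must exceed `min_umi`;
#'   default 0.05.
#' @return The gene-filtered [expr_matrix()].
#' @export
filter_genes <- function(m, min_umi = 2L, min_cell_frac = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  n_cells <- ncol(m$counts)
  if (n_cells == 0L) abort("no cells left; apply the cell filter first")
  n_expressing <- Matrix::rowSums(m$counts > min_umi)
  keep <- n_expressing / n_cells > min_cell_frac
  out <- m
  out$counts <- m$counts[keep, , drop = FALSE]
  attr(out, "gene_filter") <- list(before = nrow(m$counts),
                                   after = sum(keep), min_umi = min_umi,
                                   min_cell_frac = min_cell_frac)
  out
}

#' Compute TPM-like expression values
#'
#' Expression of gene *i* in cell *j* is the UMI count divided by the cell's
#' UMI sum, times 10,000 ("TPM-like"), plus a pseudocount of 1. No log
#' transform is applied by default; a rank test downstream is invariant to
#' monotone transforms, so `log2 = TRUE` changes reported magnitudes only.
#'
#' The denominator sums over retained genes by default (removed genes take
#' no part in downstream analyses); `denominator = "prefilter"` uses each
#' cell's UMI total from before gene filtering instead.
#'
#' @param m An [expr_matrix()] after filtering.
#' @param scale_factor Multiplier for the per-cell proportions; default
#'   10,000.
#' @param denominator `"retained"` (default) or `"prefilter"`.
#' @param log2 Apply `log2` to the (TPM-like + 1) values.
#' @return The [expr_matrix()] with `$tpm` set (sparse TPM-like values,
#'   pseudocount stored implicitly: expression = tpm + 1, see
#'   [expr_values()]).
#' @export
normalize_expression <- function(m, scale_factor = 1e4,
                                 denominator = c("retained", "prefilter"),
                                 log2 = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  denominator <- match.arg(denominator)
  cellsum <- switch(denominator,
                    retained = Matrix::colSums(m$counts),
                    prefilter = m$prefilter_cellsums)
  if (any(cellsum == 0)) abort("cell with zero retained UMIs cannot be normalized")
  out <- m
  out$tpm <- m$counts %*% Matrix::Diagonal(x = scale_factor / cellsum)
  dimnames(out$tpm) <- dimnames(m$counts)
  out$log2 <- log2
  out$scale_factor <- scale_factor
  out
}

#' Dense expression values (TPM-like + 1)
#'
#' @param m A normalized [expr_matrix()].
#' @param cells Optional cell subset (colnames).
#' @param genes Optional gene subset (rownames).
#' @return Dense genes-by-cells matrix of expression values
#'   (`tpm + 1`, or `log2(tpm + 1)` when the matrix was normalized with
#'   `log2 = TRUE`).
#' @export
expr_values <- function(m, cells = NULL, genes = NULL) {
  if (is.null(m$tpm)) abort("matrix not normalized; run normalize_expression()")
  x <- m$tpm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  x <- as.matrix(x) + 1
  if (isTRUE(m$log2)) x <- log2(x)
  x
}

#' Merge channels on their gene intersection
#'
#' Filters are per channel; merged analyses use the genes retained in every
#' channel. Cell indexes are prefixed with the channel id when a collision
#' would otherwise occur.
#'
#' @param channels List of [expr_matrix()] objects (all filtered; all
#'   normalized or all raw).
#' @return A single [expr_matrix()] spanning all cells.
#' @export
merge_channels <- function(channels) {
  stopifnot(length(channels) >= 1L)
  if (length(channels) == 1L) return(channels[[1]])
  genes <- Reduce(intersect, lapply(channels, function(m) rownames(m$counts)))
  if (length(genes) == 0L) abort("channels share no retained genes")
  all_cells <- unlist(lapply(channels, function(m) colnames(m$counts)))
  need_prefix <- anyDuplicated(all_cells) > 0L
  take <- function(m) {
    cts <- m$counts[genes, , drop = FALSE]
    if (need_prefix) colnames(cts) <- paste0(m$channel_id, ":", colnames(cts))
    cts
  }
  counts <- do.call(cbind, lapply(channels, take))
  out <- expr_matrix(counts, channel_id = paste(
    vapply(channels, function(m) m$channel_id, ""), collapse = "+"))
  out$prefilter_cellsums <- unlist(lapply(channels, function(m) {
    s <- m$prefilter_cellsums
    if (need_prefix) names(s) <- paste0(m$channel_id, ":", names(s))
    s
  }))
  if (!any(vapply(channels, function(m) is.null(m$tpm), logical(1)))) {
    tpm <- do.call(cbind, lapply(channels, function(m) {
      x <- m$tpm[genes, , drop = FALSE]
      if (need_prefix) colnames(x) <- paste0(m$channel_id, ":", colnames(x))
      x
    }))
    out$tpm <- tpm
    out$log2 <- channels[[1]]$log2
  }
  out
}

#' One-call preprocessing of a channel
#'
#' Cells first (mitochondrial filter), then genes (prevalence filter), then
#' TPM-like normalization — the stated order.
#'
#' @inheritParams filter_cells_by_mito
#' @inheritParams filter_genes
#' @inheritParams normalize_expression
#' @return A filtered, normalized [expr_matrix()].
#' @export
preprocess_channel <- function(m, mito_genes = NULL, mito_prefix = "MT-",
                               max_frac = 0.10, min_umi = 2L,
                               min_cell_frac = 0.05, scale_factor = 1e4,
                               denominator = "retained", log2 = FALSE) {
  m |>
    filter_cells_by_mito(mito_genes = mito_genes, max_frac = max_frac,
                         mito_prefix = mito_prefix) |>
    filter_genes(min_umi = min_umi, min_cell_frac = min_cell_frac) |>
    normalize_expression(scale_factor = scale_factor,
                         denominator = denominator, log2 = log2)
}
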