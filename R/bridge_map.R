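#' Scan molecular-bridge reads for cell-index / clone-barcode pairs
#'
#' A molecular bridge is a cDNA molecule carrying both the droplet cell
#' barcode (cellular cDNA index) and the clonal tracking barcode, sequenced
#' as a long-read circular consensus. A read yields a (cell, clone) pair iff
#' it contains, as exact substrings with zero mismatches, exactly one
#' whitelisted cellular index and exactly one whitelisted clone barcode.
#' Reads with two distinct whitelisted cell indexes, or two distinct
#' whitelisted clone barcodes, are discarded as ambiguous.
#'
#' Consensus reads have arbitrary strand, so by default both the sequence
#' and its reverse complement are scanned; hits from the two orientations
#' are pooled before the exactly-one rule is applied, so an orientation
#' disagreement also discards the read.
#'
#' @param reads Tibble with a `sequence` column (e.g. [read_reads()]), a
#'   character vector of sequences, or a path to a FASTA/FASTQ file.
#' @param cell_whitelist Character vector of valid cellular cDNA indexes
#'   (all the same length, typically the 16-nt droplet barcodes of the
#'   count matrix).
#' @param clone_whitelist Character vector of valid clone barcodes (all the
#'   same length).
#' @param both_strands Scan the reverse complement as well. Default `TRUE`.
#' @return Tibble `cell`, `clone`, `support` (number of reads supporting the
#'   pair).
#' @export
scan_bridge_reads <- function(reads, cell_whitelist, clone_whitelist,
                              both_strands = TRUE) {
  if (length(cell_whitelist) == 0L || length(clone_whitelist) == 0L) {
    abort("cell and clone whitelists must be non-empty")
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  seqs <- unname(if (is.data.frame(reads)) reads$sequence
                 else as.character(reads))
  if (any(!nzchar(seqs))) abort("bridge read sequences must be non-empty")

  cl_len <- unique(nchar(cell_whitelist))
  bc_len <- unique(nchar(clone_whitelist))
  if (length(cl_len) != 1L) abort("cell indexes must share one length")
  if (length(bc_len) != 1L) abort("clone barcodes must share one length")

  scan_one <- function(s) {
    hits_cell <- character(0)
    hits_clone <- character(0)
    orients <- if (both_strands) {
      c(s, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))))
    } else s
    for (o in orients) {
      hits_cell <- c(hits_cell, .substr_hits(o, cell_whitelist, cl_len))
      hits_clone <- c(hits_clone, .substr_hits(o, clone_whitelist, bc_len))
    }
    list(cell = unique(hits_cell), clone = unique(hits_clone))
  }

  hits <- lapply(seqs, scan_one)
  keep <- vapply(hits, function(h)
    length(h$cell) == 1L && length(h$clone) == 1L, logical(1))
  if (!any(keep)) {
    return(tibble(cell = character(0), clone = character(0),
                  support = integer(0)))
  }
  tibble(cell = vapply(hits[keep], function(h) h$cell, ""),
         clone = vapply(hits[keep], function(h) h$clone, "")) |>
    count(.data$cell, .data$clone, name = "support")
}

# all whitelist members occurring as exact substrings of s
.substr_hits <- function(s, whitelist, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  whitelist[whitelist %in% kmers]
}

#' Assign cells to clones from bridge-read pairs
#'
#' A cell is assigned to a clone when at least `min_support` bridge reads
#' (default 1: a single molecule suffices) name that clone and no read names
#' any other clone. Cells whose reads name two or more distinct clones are
#' excluded as multimapped; whitelisted cells with no bridge evidence are
#' unmapped. The three sets partition the cell whitelist.
#'
#' @param pairs Tibble `cell`, `clone`, `support` from [scan_bridge_reads()].
#' @param cell_whitelist Character vector of all cells with transcriptome
#'   data.
#' @param min_support Minimum supporting reads per (cell, clone) pair.
#' @return A `cell_clone_map`: list with `assignments` (tibble `cell`,
#'   `clone`, `support`), `excluded_multimapped` (character) and
#'   `unmapped_cells` (character).
#' @export
assign_cells <- function(pairs, cell_whitelist, min_support = 1L) {
  pairs <- filter(as_tibble(pairs), .data$support >= min_support)
  per_cell <- pairs |>
    group_by(.data$cell) |>
    summarise(n_clones = dplyr::n_distinct(.data$clone),
              clone = .data$clone[1], support = sum(.data$support),
              .groups = "drop")
  assigned <- filter(per_cell, .data$n_clones == 1L) |>
    select("cell", "clone", "support")
  excluded <- per_cell$cell[per_cell$n_clones > 1L]
  unmapped <- setdiff(cell_whitelist, per_cell$cell)
  new_cell_clone_map(assigned, excluded, unmapped)
}

new_cell_clone_map <- function(assignments, excluded, unmapped) {
  structure(list(assignments = as_tibble(assignments),
                 excluded_multimapped = as.character(excluded),
                 unmapped_cells = as.character(unmapped)),
            class = "cell_clone_map")
}

#' @export
print.cell_clone_map <- function(x, ...) {
  cat("cell_clone_map:", nrow(x$assignments), "assigned,",
      length(x$excluded_multimapped), "excluded (multimapped),",
      length(x$unmapped_cells), "unmapped\n")
  invisible(x)
}

#' @rdname tidy_clonotrx
#' @export
tidy.cell_clone_map <- function(x, ...) {
  bind_rows(
    mutate(x$assignments, status = "assigned"),
    tibble(cell = x$excluded_multimapped, clone = NA_character_,
           support = NA_integer_, status = "multimapped"),
    tibble(cell = x$unmapped_cells, clone = NA_character_,
           support = NA_integer_, status = "unmapped"))
}

#' Read/write a cell-to-clone map as TSV
#'
#' The map is serialized as one TSV with columns `cell`, `clone`, `support`,
#' `status` (`assigned` | `multimapped` | `unmapped`).
#'
#' @param map A `cell_clone_map`.
#' @param path Output TSV path.
#' @return `path` (write) / a `cell_clone_map` (read).
#' @export
write_cell_clone_map <- function(map, path) {
  utils::write.table(tidy(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_clone_map
#' @export
read_cell_clone_map <- function(path) {
  tb <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    colClasses = c("character", "character",
                                                   "integer", "character")))
  new_cell_clone_map(
    assignments = select(filter(tb, .data$status == "assigned"),
                         "cell", "clone", "support"),
    excluded = tb$cell[tb$status == "multimapped"],
    unmapped = tb$cell[tb$status == "unmapped"])
}
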