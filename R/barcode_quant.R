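#' Describe the barcode amplicon architecture
#'
#' A clonal tracking barcode is a fixed-length random sequence inserted in the
#' 3'UTR of the GFP transgene, amplified with constant flanking sequence on
#' both sides. Extraction needs only the two flanks and the barcode length.
#'
#' @param flank5 Constant sequence immediately upstream of the barcode
#'   (uppercase ACGT).
#' @param flank3 Constant sequence immediately downstream of the barcode.
#' @param bc_len Barcode length in nucleotides.
#' @return A `barcode_spec` object (list with `flank5`, `flank3`, `bc_len`).
#' @examples
#' barcode_spec("ACGTACGT", "TTGGCCAA", 30)
#' @export
barcode_spec <- function(flank5, flank3, bc_len) {
  stopifnot(is.character(flank5), length(flank5) == 1L,
            is.character(flank3), length(flank3) == 1L)
  if (nchar(flank5) == 0L || nchar(flank3) == 0L) {
    abort("flanks must be non-empty")
  }
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    abort("flanks must be uppercase ACGT only")
  }
  bc_len <- as.integer(bc_len)
  if (is.na(bc_len) || bc_len <= 0L) abort("bc_len must be a positive integer")
  structure(list(flank5 = flank5, flank3 = flank3, bc_len = bc_len),
            class = "barcode_spec")
}

#' Read sequencing reads into a tibble
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] accepting FASTQ or
#' FASTA (gzip allowed, inferred from the file name).
#'
#' @param path Path to a FASTQ/FASTA file.
#' @return A tibble with columns `read_id`, `sequence`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) abort(paste0("read file not found: ", path))
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = names(ss) %||% as.character(seq_along(ss)),
         sequence = as.character(ss))
}

#' Write reads to FASTQ or FASTA
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output path; format chosen from the extension
#'   (`.fastq`/`.fq` vs anything else = FASTA).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  if (fmt == "fastq") {
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::PhredQuality(
                                  vapply(width(ss), function(w)
                                    paste(rep("I", w), collapse = ""), "")))
  } else {
    Biostrings::writeXStringSet(ss, path, format = "fasta")
  }
  invisible(path)
}

width <- function(ss) Biostrings::width(ss)

#' Extract and count clonal tracking barcodes from amplicon reads
#'
#' Each read contributes at most one barcode: the fixed-length substring
#' found between exact (error-free) matches of the upstream and downstream
#' flanks, scanning the forward strand at the first admissible position.
#' Reads without both flanks in that arrangement, or whose candidate barcode
#' contains non-ACGT characters, are tallied as unparsed.
#'
#' @param reads A tibble with a `sequence` column (e.g. from [read_reads()]),
#'   or a character vector of read sequences, or a path to a FASTQ/FASTA file.
#' @param spec A [barcode_spec()].
#' @param revcomp Also scan the reverse complement of reads that fail on the
#'   forward strand. Default `FALSE`: amplicon sequencing is directional.
#' @return A `barcode_counts` tibble with columns `barcode`, `count`, sorted
#'   by decreasing count, carrying attributes `total_reads` (sum of counts)
#'   and `n_unparsed`.
#' @examples
#' spec <- barcode_spec("AACCGGTT", "GGTTAACC", 4)
#' extract_barcodes(c("TTAACCGGTTACGTGGTTAACCTT"), spec)
#' @export
extract_barcodes <- function(reads, spec, revcomp = FALSE) {
  stopifnot(inherits(spec, "barcode_spec"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  seqs <- unname(if (is.data.frame(reads)) reads$sequence
                 else as.character(reads))
  if (length(seqs) == 0L) abort("no reads")

  bc <- .match_barcode(seqs, spec)
  if (revcomp) {
    miss <- is.na(bc)
    if (any(miss)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[miss])))
      bc[miss] <- .match_barcode(rc, spec)
    }
  }
  n_unparsed <- sum(is.na(bc))
  if (n_unparsed == length(seqs)) {
    warn("no read contained both flanks; all reads unparsed")
  }
  tab <- table(bc[!is.na(bc)])
  out <- tibble(barcode = as.character(names(tab) %||% character(0)),
                count = as.integer(tab)) |>
    arrange(dplyr::desc(.data$count), .data$barcode)
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "n_unparsed") <- n_unparsed
  class(out) <- c("barcode_counts", class(out))
  out
}

.match_barcode <- function(seqs, spec) {
  pat <- paste0(spec$flank5, "([ACGT]{", spec$bc_len, "})", spec$flank3)
  m <- regexpr(pat, seqs)
  ok <- m > 0L
  out <- rep(NA_character_, length(seqs))
  out[ok] <- substr(seqs[ok], m[ok] + nchar(spec$flank5),
                    m[ok] + nchar(spec$flank5) + spec$bc_len - 1L)
  out
}

#' Collapse sequencing-error barcodes into abundant neighbors
#'
#' Optional error-absorption step: each barcode is merged into the
#' highest-count barcode within Hamming distance `max_dist`, greedily from
#' the most abundant down. `max_dist = 0` (the default used by the pipeline)
#' leaves counts untouched — exact counting is the stated procedure.
#'
#' @param counts A `barcode_counts` tibble (`barcode`, `count`).
#' @param max_dist Maximum Hamming distance absorbed. 0 disables collapsing.
#' @return A `barcode_counts` tibble of the same shape.
#' @export
collapse_barcodes <- function(counts, max_dist = 0L) {
  if (max_dist <= 0L || nrow(counts) < 2L) return(counts)
  bcs <- counts$barcode
  cts <- counts$count
  ord <- order(-cts, bcs)
  bcs <- bcs[ord]; cts <- cts[ord]
  target <- seq_along(bcs)
  mat <- do.call(rbind, strsplit(bcs, ""))
  for (i in rev(seq_along(bcs))[-length(bcs)]) {
    for (j in seq_len(i - 1L)) {
      if (sum(mat[i, ] != mat[j, ]) <= max_dist) {
        target[i] <- j
        break
      }
    }
  }
  # follow chains to terminal parents
  repeat {
    nxt <- target[target]
    if (identical(nxt, target)) break
    target <- nxt
  }
  agg <- rowsum(cts, group = bcs[target])
  out <- tibble(barcode = rownames(agg), count = as.integer(agg[, 1])) |>
    arrange(dplyr::desc(.data$count), .data$barcode)
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "n_unparsed") <- attr(counts, "n_unparsed")
  class(out) <- c("barcode_counts", class(out))
  out
}

#' Convert barcode read counts to FACS-scaled clonal abundance
#'
#' Clonal abundance expresses each clone as a percentage of all mononuclear
#' cells (MNC):
#' \deqn{abundance_b = 100 \times \frac{reads_b}{total\ reads} \times
#'   \frac{human}{MNC} \times \frac{GFP^{+}}{human}}
#' so the per-sample abundance sum equals
#' `100 * frac_human_of_mnc * frac_gfp_of_human` before any filtering.
#'
#' @param counts A tibble of read counts with columns `sample_id`, `barcode`,
#'   `count` — or a single-sample `barcode_counts` tibble together with a
#'   one-row `meta`.
#' @param meta Sample metadata with columns `sample_id`,
#'   `frac_human_of_mnc`, `frac_gfp_of_human` (other columns carried along by
#'   downstream joins, not needed here).
#' @return A tibble `sample_id`, `barcode`, `abundance` (% of MNC).
#' @examples
#' counts <- tibble::tibble(sample_id = "s1",
#'                          barcode = c("AAAA", "CCCC"), count = c(50L, 50L))
#' meta <- tibble::tibble(sample_id = "s1", frac_human_of_mnc = 0.5,
#'                        frac_gfp_of_human = 0.5)
#' compute_clonal_abundance(counts, meta)  # 12.5% each
#' @export
compute_clonal_abundance <- function(counts, meta) {
  if (!"sample_id" %in% names(counts)) {
    if (nrow(meta) != 1L) {
      abort("counts without sample_id need a single-row meta")
    }
    counts <- mutate(as_tibble(counts), sample_id = meta$sample_id)
  }
  need <- c("sample_id", "frac_human_of_mnc", "frac_gfp_of_human")
  if (!all(need %in% names(meta))) {
    abort(paste0("meta must contain columns: ", paste(need, collapse = ", ")))
  }
  if (anyNA(meta$frac_human_of_mnc) || anyNA(meta$frac_gfp_of_human)) {
    abort("missing FACS fraction in meta")
  }
  if (any(meta$frac_human_of_mnc < 0 | meta$frac_human_of_mnc > 1) ||
      any(meta$frac_gfp_of_human < 0 | meta$frac_gfp_of_human > 1)) {
    abort("FACS fractions must lie in [0, 1]")
  }
  counts <- as_tibble(counts)
  tot <- counts |> group_by(.data$sample_id) |>
    summarise(total_reads = sum(.data$count), .groups = "drop")
  if (any(tot$total_reads == 0)) abort("no barcode reads")
  missing_meta <- setdiff(counts$sample_id, meta$sample_id)
  if (length(missing_meta)) {
    abort(paste0("samples missing from meta: ",
                 paste(missing_meta, collapse = ", ")))
  }
  counts |>
    left_join(tot, by = "sample_id") |>
    left_join(select(meta, "sample_id", "frac_human_of_mnc",
                     "frac_gfp_of_human"), by = "sample_id") |>
    mutate(abundance = 100 * .data$count / .data$total_reads *
             .data$frac_human_of_mnc * .data$frac_gfp_of_human) |>
    select("sample_id", "barcode", "abundance")
}

#' Apply the clonal detection filter
#'
#' Clones with an abundance strictly greater than `threshold` (% of MNC) are
#' retained; everything else is zeroed. Filtering is per sample — a clone may
#' pass in spleen and fail in blood. Clones zeroed in every sample are
#' dropped. Idempotent.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance` from
#'   [compute_clonal_abundance()].
#' @param threshold Detection threshold in % of MNC; default 0.01.
#' @return Filtered tibble of the same shape, with `threshold` attached as an
#'   attribute.
#' @export
filter_clones <- function(abundance, threshold = 0.01) {
  if (threshold < 0) abort("threshold must be non-negative")
  out <- abundance |>
    mutate(abundance = ifelse(.data$abundance > threshold,
                              .data$abundance, 0)) |>
    group_by(.data$barcode) |>
    filter(any(.data$abundance > 0)) |>
    ungroup()
  attr(out, "threshold") <- threshold
  out
}

#' Pivot a long abundance table to a samples-by-clones matrix
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @return Numeric matrix, rows = samples, columns = clone barcodes; clones
#'   undetected in a sample are 0.
#' @export
abundance_matrix <- function(abundance) {
  wide <- abundance |>
    tidyr::pivot_wider(names_from = "barcode", values_from = "abundance",
                       values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
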