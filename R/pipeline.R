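#' Run the full clonal-tracking pipeline
#'
#' Chains quantify (barcode extraction + FACS-scaled abundance + detection
#' filter), map-bridges, preprocess (mito/gene filters + TPM-like
#' normalization, per channel, merged on the gene intersection), stats
#' (Shannon diversity, cross-sample Pearson correlation) and, when a clone
#' grouping is supplied, differential expression with the false-positive
#' score. Every stage writes CSV/TSV outputs under `out_dir` and a
#' `manifest.json` records all parameters, seeds and per-stage row/column
#' counts. A failing stage aborts with its name; a `.partial` marker file
#' flags incomplete output directories.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `fastqs` (named vector sample_id -> FASTQ path), `meta` (CSV path),
#'   `flank5`, `flank3`, `bc_len`, optional `threshold` (default 0.01),
#'   optional `collapse_dist` (default 0), optional `bridges` (FASTA path),
#'   `channels` (vector of MTX directories), optional `mito_prefix`
#'   (default `"MT-"`), `max_mito` (0.10), `min_umi` (2), `min_cell_frac`
#'   (0.05), optional `groups` (list with `group_a`, `group_b`, `direction`,
#'   `label`, or path to such a JSON), `n_scrambles` (5), `seed` (0).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .pipeline_defaults(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  manifest <- list(parameters = cfg[setdiff(names(cfg),
                                            c("fastqs", "channels"))],
                   stages = list())
  res <- list()

  run_stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    out
  }

  # -- quantify ---------------------------------------------------------
  res$abundance <- run_stage("quantify", function() {
    if (!file.exists(cfg$meta)) {
      abort(paste0("metadata file not found: ", cfg$meta))
    }
    meta <- as_tibble(read.csv(cfg$meta, colClasses = c(
      sample_id = "character")))
    spec <- barcode_spec(cfg$flank5, cfg$flank3, cfg$bc_len)
    counts <- imap(cfg$fastqs, function(fp, sid) {
      ct <- extract_barcodes(fp, spec)
      if (cfg$collapse_dist > 0) ct <- collapse_barcodes(ct, cfg$collapse_dist)
      mutate(ct, sample_id = sid)
    }) |> bind_rows()
    ab <- compute_clonal_abundance(counts, meta) |>
      filter_clones(threshold = cfg$threshold)
    write.csv(abundance_matrix(ab) |> round(6) |> as.data.frame() |>
                tibble::rownames_to_column("sample_id"),
              file.path(out_dir, "abundance.csv"), row.names = FALSE)
    utils::write.table(counts, file.path(out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$quantify <<- list(
      n_samples = length(unique(ab$sample_id)),
      n_clones = length(unique(ab$barcode)))
    attr(ab, "meta") <- meta
    ab
  })
  meta <- attr(res$abundance, "meta")

  # -- preprocess -------------------------------------------------------
  if (length(cfg$channels)) {
    res$expr <- run_stage("preprocess", function() {
      chans <- lapply(cfg$channels, function(d) {
        read_mtx_channel(d) |>
          preprocess_channel(mito_prefix = cfg$mito_prefix,
                             max_frac = cfg$max_mito, min_umi = cfg$min_umi,
                             min_cell_frac = cfg$min_cell_frac)
      })
      merged <- merge_channels(chans)
      write_mtx_channel(merged, file.path(out_dir, "filtered"),
                        params = list(max_mito = cfg$max_mito,
                                      min_umi = cfg$min_umi,
                                      min_cell_frac = cfg$min_cell_frac,
                                      cells_per_channel = lapply(
                                        chans, function(m)
                                          attr(m, "cell_filter"))))
      manifest$stages$preprocess <<- list(
        n_genes = nrow(merged$counts), n_cells = ncol(merged$counts))
      merged
    })
  }

  # -- map-bridges ------------------------------------------------------
  if (!is.null(cfg$bridges)) {
    res$map <- run_stage("map_bridges", function() {
      clone_wl <- unique(res$abundance$barcode)
      cell_wl <- colnames(res$expr$counts)
      pairs <- scan_bridge_reads(cfg$bridges, cell_wl, clone_wl)
      map <- assign_cells(pairs, cell_wl)
      write_cell_clone_map(map, file.path(out_dir, "cell_clone_map.tsv"))
      manifest$stages$map_bridges <<- list(
        n_assigned = nrow(map$assignments),
        n_multimapped = length(map$excluded_multimapped),
        n_unmapped = length(map$unmapped_cells))
      map
    })
  }

  # -- stats ------------------------------------------------------------
  res$stats <- run_stage("stats", function() {
    div <- shannon_diversity(res$abundance)
    write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    corr <- NULL
    if (length(unique(res$abundance$sample_id)) >= 2L) {
      corr <- pearson_cross_tissue(res$abundance)
      write.csv(as.data.frame(corr) |>
                  tibble::rownames_to_column("sample_id"),
                file.path(out_dir, "correlation.csv"), row.names = FALSE)
    }
    manifest$stages$stats <<- list(n_samples = nrow(div))
    list(diversity = div, correlation = corr)
  })

  # -- dge --------------------------------------------------------------
  if (!is.null(cfg$groups) && !is.null(res$map) && !is.null(res$expr)) {
    res$dge <- run_stage("dge", function() {
      g <- cfg$groups
      if (is.character(g)) g <- jsonlite::read_json(g, simplifyVector = TRUE)
      grouping <- clone_grouping(g$group_a, g$group_b,
                                 direction = g$direction %||% "a_greater",
                                 label = g$label %||% "")
      d <- dge_fps(res$expr, res$map, grouping,
                   n_scrambles = cfg$n_scrambles, seed = cfg$seed)
      write_dge(d, file.path(out_dir, "dge.csv"))
      manifest$stages$dge <<- as.list(glance(d))
      d
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  res$manifest <- manifest
  invisible(res)
}

.pipeline_defaults <- function(config) {
  defaults <- list(threshold = 0.01, collapse_dist = 0L, bridges = NULL,
                   channels = character(0), mito_prefix = "MT-",
                   max_mito = 0.10, min_umi = 2L, min_cell_frac = 0.05,
                   groups = NULL, n_scrambles = 5L, seed = 0L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  for (k in c("fastqs", "meta", "flank5", "flank3", "bc_len")) {
    if (is.null(config[[k]])) abort(paste0("pipeline config misses '", k, "'"))
  }
  config
}
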