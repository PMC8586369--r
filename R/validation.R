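#' Validation studies with known ground truth
#'
#' Each function runs a frozen simulation study against the pipeline and
#' returns the per-replicate outcome, so the package's operating
#' characteristics (null false-discovery behavior, power on planted fold
#' changes, tissue-bias calibration, end-to-end exactness) can be
#' recomputed from scratch at any time. Study conditions are fixed inside
#' the functions; only the replicate count and master seed vary.
#'
#' @param n_sims Number of replicate simulations.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return A tibble with one row per replicate (see each function).
#' @name validation
NULL

# truth map: every simulated cell mapped to its clone, no exclusions
.truth_map <- function(cell_clones) {
  new_cell_clone_map(
    tibble(cell = cell_clones$cell,
           clone = paste0("B", cell_clones$clone), support = 1L),
    character(0), character(0))
}

#' @describeIn validation Null false-discovery control: 500 genes, 200
#'   mapped cells over 20 clones split into two arbitrary groups of 10,
#'   no planted expression difference. Returns `n_sig` (significant genes
#'   under FPS < 0.05 and p < 0.05) and `n_genes` (genes tested) per
#'   replicate; the mean of `n_sig` is the quantity of interest.
#' @export
validate_null_fdr <- function(n_sims = 100L, seed = 0L) {
  res <- lapply(seq_len(n_sims), function(r) {
    cfg <- sim_config(n_clones = 20, n_cells = 200, n_genes = 500,
                      frac_high_mito = 0, seed = seed + r)
    cc <- simulate_cell_clones(cfg)
    sc <- simulate_sc_counts(cfg, cc)
    m <- preprocess_channel(expr_matrix(sc$counts))
    g <- clone_grouping(paste0("B", 1:10), paste0("B", 11:20), "a_greater")
    d <- dge_fps(m, .truth_map(cc), g, seed = (seed + r) * 10)
    tibble(sim = r, n_sig = sum(d$results$significant),
           n_genes = nrow(d$results))
  })
  bind_rows(res)
}

#' @describeIn validation Power / parameter recovery: 10 genes planted at a
#'   2-fold mean shift between two clone groups of ~125 cells each (250
#'   cells over 10 clones, 500 genes). Returns `n_recovered` (planted genes
#'   called significant, of `n_planted`) per replicate.
#' @export
validate_power <- function(n_sims = 50L, seed = 0L) {
  res <- lapply(seq_len(n_sims), function(r) {
    cfg <- sim_config(n_clones = 10, n_cells = 250, n_genes = 500,
                      frac_high_mito = 0,
                      planted_de = tibble(gene = 1:10, group = "a",
                                          fold = 2),
                      de_group_a = 1:5, de_group_b = 6:10, seed = seed + r)
    cc <- simulate_cell_clones(cfg)
    sc <- simulate_sc_counts(cfg, cc)
    m <- preprocess_channel(expr_matrix(sc$counts))
    g <- clone_grouping(paste0("B", 1:5), paste0("B", 6:10), "a_greater")
    d <- dge_fps(m, .truth_map(cc), g, seed = (seed + r) * 10)
    sig <- d$results$gene[d$results$significant]
    tibble(sim = r,
           n_recovered = sum(sc$truth$planted_genes %in% sig),
           n_planted = length(sc$truth$planted_genes))
  })
  bind_rows(res)
}

#' @describeIn validation Tissue-bias calibration: 50-clone cohorts with
#'   blood, spleen and ovary samples at 1e5 reads each. With
#'   `planted = TRUE`, clones 1-5 carry a 10x ovary multiplier and
#'   `recall` is the fraction of them called tissue-biased; neutral clones
#'   should rarely be called either way (`fp` of `n_neutral`). With
#'   `planted = FALSE` the cohort is fully neutral and the call rate
#'   estimates the band's false-call rate.
#' @param planted Plant 10x ovary-tropic clones (see above).
#' @export
validate_tissue_bias <- function(n_sims = 200L, seed = 0L, planted = TRUE) {
  res <- lapply(seq_len(n_sims), function(r) {
    tb <- if (planted) {
      tibble(clone = 1:5, tissue = "ovary", multiplier = 10)
    } else NULL
    cfg <- sim_config(n_clones = 50, n_mice = 1,
                      tissues = c("blood", "spleen", "ovary"),
                      tissue_bias = tb, frac_human_of_mnc = 0.5,
                      frac_gfp_of_human = 0.15, read_depth = 1e5,
                      seed = seed + r)
    props <- simulate_clone_proportions(cfg)
    bcs <- paste0("BC", sprintf("%02d", seq_len(cfg$n_clones)))
    ab <- withr::with_seed(seed + r + 7L, bind_rows(
      lapply(unique(props$sample_id), function(s) {
        pr <- props[props$sample_id == s, ]
        counts <- tibble(sample_id = s, barcode = bcs,
                         count = as.integer(rmultinom(1, cfg$read_depth,
                                                      pr$proportion)))
        compute_clonal_abundance(counts, tibble(
          sample_id = s, frac_human_of_mnc = cfg$frac_human_of_mnc,
          frac_gfp_of_human = min(1, cfg$frac_gfp_of_human * pr$scale[1])))
      })))
    calls <- tissue_bias(ab, "m1_blood", "m1_spleen", "m1_ovary")
    planted_bc <- if (planted) bcs[1:5] else character(0)
    neutral <- calls[!calls$clone %in% planted_bc, ]
    tibble(sim = r,
           recall = if (planted) {
             mean(calls$call[calls$clone %in% planted_bc] == "tissue_biased")
           } else NA_real_,
           fp = sum(neutral$call != "unbiased"),
           n_neutral = nrow(neutral))
  })
  bind_rows(res)
}

#' @describeIn validation Mapped-cell fraction: one channel of 2,000 cells
#'   with bridge coverage 0.2 and 2% multimap contamination, mapped with
#'   the exact-match rules. Returns the assigned fraction (the ~20% the
#'   bridge protocol achieves) and the exclusion counts.
#' @export
validate_mapped_fraction <- function(seed = 0L) {
  cfg <- sim_config(n_clones = 20, n_cells = 2000, seed = seed)
  bcs <- simulate_barcodes(cfg$n_clones, cfg$barcode_len, seed = seed + 1L)
  cc <- simulate_cell_clones(cfg)
  br <- simulate_bridge_reads(cc, bcs, coverage = cfg$bridge_coverage,
                              multimap_rate = cfg$bridge_multimap_rate,
                              seed = seed + 2L)
  map <- assign_cells(scan_bridge_reads(br, cc$cell, bcs), cc$cell)
  tibble(n_cells = nrow(cc), n_assigned = nrow(map$assignments),
         n_multimapped = length(map$excluded_multimapped),
         n_unmapped = length(map$unmapped_cells),
         mapped_fraction = nrow(map$assignments) / nrow(cc))
}

#' @describeIn validation End-to-end round trip on a noise-free cohort
#'   (no sequencing errors, no bridge contamination): runs the full
#'   pipeline and compares every stage against generator truth. Returns
#'   one row with `counts_exact` (extracted read counts equal the realized
#'   multinomial draw in every sample), `assignments_exact` (every covered
#'   cell assigned its true clone, none excluded), `planted_recovered` /
#'   `n_planted` (planted 8-fold genes called significant) and
#'   `n_extra_calls`.
#' @param dir Scratch directory for the simulated cohort and pipeline
#'   output.
#' @export
validate_roundtrip <- function(seed = 0L, dir = tempfile("roundtrip")) {
  cfg <- sim_config(n_clones = 6, n_mice = 1, read_depth = 5000,
                    n_cells = 400, n_genes = 150, bridge_coverage = 0.6,
                    bridge_multimap_rate = 0, error_rate = 0,
                    planted_de = tibble(gene = c(10L, 25L, 40L),
                                        group = "a", fold = 8),
                    de_group_a = 1:3, de_group_b = 4:6, seed = seed)
  sim_dir <- file.path(dir, "sim")
  sim <- simulate_cohort(cfg, sim_dir)
  fastqs <- sim$paths$fastqs
  names(fastqs) <- sub("\\.fastq$", "", basename(fastqs))
  out <- file.path(dir, "out")
  res <- run_pipeline(list(
    fastqs = fastqs, meta = sim$paths$meta, flank5 = cfg$flank5,
    flank3 = cfg$flank3, bc_len = cfg$barcode_len,
    bridges = sim$paths$bridges, channels = sim$paths$channel,
    groups = list(group_a = sim$truth$clone_barcodes[1:3],
                  group_b = sim$truth$clone_barcodes[4:6],
                  direction = "a_greater", label = "planted"),
    seed = seed), out)

  counts <- utils::read.table(file.path(out, "counts.tsv"), header = TRUE,
                              colClasses = c("character", "integer",
                                             "character"))
  counts_exact <- all(vapply(names(sim$truth$true_counts), function(sid) {
    got <- counts[counts$sample_id == sid, ]
    tc <- setNames(sim$truth$true_counts[[sid]], sim$truth$clone_barcodes)
    tc <- tc[tc > 0]
    setequal(got$barcode, names(tc)) &&
      all(setNames(got$count, got$barcode)[names(tc)] == tc)
  }, logical(1)))

  truth_map <- setNames(sim$truth$cell_clones$barcode,
                        sim$truth$cell_clones$cell)
  am <- res$map$assignments
  # bridge mapping runs against the cells that survive the mito filter
  expected_cells <- intersect(sim$truth$covered_cells,
                              colnames(res$expr$counts))
  assignments_exact <-
    setequal(am$cell, expected_cells) &&
    all(am$clone == unname(truth_map[am$cell])) &&
    length(res$map$excluded_multimapped) == 0L

  sig <- res$dge$results$gene[res$dge$results$significant]
  tibble(counts_exact = counts_exact,
         assignments_exact = assignments_exact,
         planted_recovered = sum(sim$truth$planted_genes %in% sig),
         n_planted = length(sim$truth$planted_genes),
         n_extra_calls = length(setdiff(sig, sim$truth$planted_genes)))
}
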