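#' Configuration for a synthetic clonal-tracking cohort
#'
#' Bundles every knob of the generator with cohort-scale defaults: 50
#' lognormally sized clones, 3 mice, two tissues, 1e5 amplicon reads per
#' sample, one 10x channel of 1,000 cells over 500 genes with
#' negative-binomial UMI counts, 20% bridge coverage. All randomness flows
#' from the single `seed`.
#'
#' @param n_clones Number of clones (>= 2).
#' @param clone_meanlog,clone_sdlog Lognormal parameters of clone sizes.
#' @param tissues Tissue labels sampled per mouse; the first is the
#'   reference ("blood"-like) compartment.
#' @param tissue_bias Optional tibble `clone` (integer index), `tissue`,
#'   `multiplier` planting tissue-tropic clones.
#' @param n_mice Mice per cohort.
#' @param read_depth Amplicon reads per sample.
#' @param frac_human_of_mnc,frac_gfp_of_human FACS fractions written into
#'   the metadata of every sample.
#' @param n_cells Cells per 10x channel.
#' @param n_genes Genes, including `n_mito_genes` mitochondrial ones
#'   (symbols `MT-1`...).
#' @param gene_meanlog,gene_sdlog Lognormal law of relative gene expression
#'   weights.
#' @param nb_dispersion Negative-binomial dispersion theta
#'   (variance = mu + mu^2/theta) of nuclear gene counts.
#' @param libsize_mean,libsize_sdlog Expected nuclear UMIs per cell and the
#'   lognormal spread of per-cell library size.
#' @param n_mito_genes Number of mitochondrial genes.
#' @param mito_beta_a,mito_beta_b Beta law of the baseline mitochondrial
#'   fraction (defaults give ~3% mean, truncated at `mito_trunc`).
#' @param mito_trunc Upper truncation of baseline mito fractions, keeping
#'   ordinary cells clear of the 10% exclusion boundary.
#' @param frac_high_mito Fraction of cells planted as dying/high-mito
#'   (target fraction uniform in `high_mito_range`).
#' @param high_mito_range Range of planted high-mito target fractions.
#' @param planted_de Tibble `gene`, `group` (`"a"` or `"b"`), `fold`
#'   (> 0) of planted expression differences.
#' @param planted_weight_quantile Planted DE genes are given this quantile
#'   of the expression-weight distribution (default 0.75) so their baseline
#'   expression is representative and recovery measures the test rather
#'   than the prevalence filter; `NULL` keeps their random weights.
#' @param de_group_a,de_group_b Integer clone indexes forming the two
#'   behavior groups for planted differences.
#' @param bridge_coverage Fraction of cells emitting at least one correct
#'   bridge read (the mapped-cell fraction the mapper should recover).
#' @param bridge_multimap_rate Fraction of covered cells additionally
#'   emitting a read naming a wrong clone (forcing exclusion).
#' @param barcode_len,cell_index_len Lengths of clone barcodes and cellular
#'   cDNA indexes (nt).
#' @param flank5,flank3 Constant flanks of the barcode amplicon.
#' @param error_rate Per-base substitution rate of amplicon reads.
#' @param n_passages Serial-transplant generations (>= 2 enables trajectory
#'   truth).
#' @param fitness_sdlog Lognormal spread of per-clone fitness across
#'   passages.
#' @param seed Master seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_clones = 50L,
                       clone_meanlog = 0, clone_sdlog = 1,
                       tissues = c("blood", "spleen"),
                       tissue_bias = NULL,
                       n_mice = 3L,
                       read_depth = 1e5,
                       frac_human_of_mnc = 0.5, frac_gfp_of_human = 0.5,
                       n_cells = 1000L, n_genes = 500L,
                       gene_meanlog = log(2), gene_sdlog = 1,
                       nb_dispersion = 2,
                       libsize_mean = 1000, libsize_sdlog = 0.3,
                       n_mito_genes = 10L,
                       mito_beta_a = 2, mito_beta_b = 60, mito_trunc = 0.06,
                       frac_high_mito = 0.05,
                       high_mito_range = c(0.15, 0.35),
                       planted_de = NULL,
                       planted_weight_quantile = 0.75,
                       de_group_a = NULL, de_group_b = NULL,
                       bridge_coverage = 0.2, bridge_multimap_rate = 0.02,
                       barcode_len = 30L, cell_index_len = 16L,
                       flank5 = "TAGCTTGGCACTGGCCGTCG",
                       flank3 = "CGTACGCTGCAGGTCGACAA",
                       error_rate = 0,
                       n_passages = 1L, fitness_sdlog = 0.5,
                       seed = 0L) {
  cfg <- as.list(environment())
  if (cfg$n_clones < 2L) abort("n_clones must be >= 2")
  fr <- c(frac_human_of_mnc, frac_gfp_of_human, frac_high_mito,
          bridge_coverage, bridge_multimap_rate)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (!is.null(planted_de)) {
    if (any(planted_de$fold <= 0)) abort("planted fold changes must be > 0")
    if (any(planted_de$gene > n_genes - n_mito_genes)) {
      abort("planted DE gene index exceeds the number of nuclear genes")
    }
    if (is.null(de_group_a) || is.null(de_group_b)) {
      abort("planted_de requires de_group_a and de_group_b")
    }
  }
  if (!is.null(de_group_a) && (any(de_group_a > n_clones) ||
                               any(de_group_b > n_clones))) {
    abort("DE group clone index exceeds n_clones")
  }
  if (length(intersect(de_group_a, de_group_b))) {
    abort("DE clone groups must be disjoint")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rand_seq <- function(n, len) {
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1, paste, collapse = "")
}

#' Draw distinct random barcodes
#'
#' @param n Number of barcodes.
#' @param len Length (nt).
#' @param seed Seed.
#' @return Character vector of `n` distinct sequences.
#' @export
simulate_barcodes <- function(n, len, seed = 0L) {
  withr::with_seed(seed, {
    out <- unique(.rand_seq(n, len))
    while (length(out) < n) {
      out <- unique(c(out, .rand_seq(n - length(out), len)))
    }
    out
  })
}

#' Simulate per-sample clone proportions
#'
#' Each mouse draws lognormal clone sizes; each tissue multiplies the
#' planted tissue-tropic clones by their bias multiplier. Sequencing sees
#' within-sample proportions, but a tissue where clones expanded holds more
#' barcoded cells in absolute terms: the per-sample `scale` column
#' (biased / unbiased total weight) records that factor so the cohort
#' writer can fold it into the GFP FACS fraction, keeping absolute clone
#' abundances comparable across tissues (a neutral clone has the same
#' expected % of MNC everywhere).
#'
#' @param cfg A [sim_config()].
#' @return Tibble `sample_id`, `mouse_id`, `tissue`, `clone` (index),
#'   `proportion` (sums to 1 per sample), `scale`.
#' @export
simulate_clone_proportions <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    out <- list()
    for (m in seq_len(cfg$n_mice)) {
      base <- rlnorm(cfg$n_clones, cfg$clone_meanlog, cfg$clone_sdlog)
      for (tis in cfg$tissues) {
        w <- base
        if (!is.null(cfg$tissue_bias)) {
          hit <- cfg$tissue_bias[cfg$tissue_bias$tissue == tis, ]
          w[hit$clone] <- w[hit$clone] * hit$multiplier
        }
        out[[length(out) + 1L]] <- tibble(
          sample_id = paste0("m", m, "_", tis),
          mouse_id = paste0("m", m), tissue = tis,
          clone = seq_len(cfg$n_clones), proportion = w / sum(w),
          scale = sum(w) / sum(base))
      }
    }
    bind_rows(out)
  })
}

#' Simulate barcode amplicon reads for one sample
#'
#' Reads are a multinomial draw over clones at the given proportions; each
#' read is flank5 + barcode + flank3 with optional uniform per-base
#' substitution errors.
#'
#' @param proportions Numeric vector summing to 1 over clones.
#' @param barcodes Clone barcode sequences, parallel to `proportions`.
#' @param depth Number of reads (> 0).
#' @param spec A [barcode_spec()].
#' @param error_rate Per-base substitution probability.
#' @param seed Seed.
#' @return Tibble `read_id`, `sequence`, `true_clone` (index) with the
#'   realized per-clone read counts in attribute `true_counts`.
#' @export
simulate_barcode_reads <- function(proportions, barcodes, depth, spec,
                                   error_rate = 0, seed = 0L) {
  if (depth <= 0) abort("depth must be positive")
  if (abs(sum(proportions) - 1) > 1e-8) abort("proportions must sum to 1")
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1, depth, proportions))
    idx <- rep(seq_along(barcodes), counts)
    seqs <- paste0(spec$flank5, barcodes[idx], spec$flank3)
    if (error_rate > 0) seqs <- .mutate_seqs(seqs, error_rate)
    tb <- tibble(read_id = paste0("r", seq_along(seqs)), sequence = seqs,
                 true_clone = idx)
    attr(tb, "true_counts") <- counts
    tb
  })
}

.mutate_seqs <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate the true cell-to-clone assignment of a 10x channel
#'
#' Cells draw their clone from the channel's clone proportions (the first
#' tissue of the first mouse by default in [simulate_cohort()]).
#'
#' @param cfg A [sim_config()].
#' @param proportions Clone proportions the loaded cells follow; default
#'   uniform over clones.
#' @return Tibble `cell` (cellular cDNA index), `clone` (index).
#' @export
simulate_cell_clones <- function(cfg, proportions = NULL) {
  proportions <- proportions %||% rep(1 / cfg$n_clones, cfg$n_clones)
  withr::with_seed(cfg$seed + 202L, {
    cells <- simulate_barcodes(cfg$n_cells, cfg$cell_index_len,
                               seed = cfg$seed + 203L)
    tibble(cell = cells,
           clone = sample.int(cfg$n_clones, cfg$n_cells, replace = TRUE,
                              prob = proportions))
  })
}

#' Simulate a UMI count matrix with planted structure
#'
#' Nuclear gene counts are negative binomial around lognormal gene weights
#' scaled by a lognormal per-cell library size; planted DE genes have their
#' mean multiplied by `fold` in cells of the designated clone group.
#' Mitochondrial counts are Poisson around a per-cell target fraction —
#' a baseline beta draw truncated well below the 10% exclusion boundary for
#' ordinary cells, and a uniform draw from `high_mito_range` for the
#' planted high-mito (dying) cells — so the planted cells, and only they,
#' exceed the filter threshold.
#'
#' @param cfg A [sim_config()].
#' @param cell_clones Tibble `cell`, `clone` from [simulate_cell_clones()].
#' @return List: `counts` (sparse genes x cells), `truth` (list with
#'   `planted_genes`, `high_mito_cells`, `group_a_cells`, `group_b_cells`).
#' @export
simulate_sc_counts <- function(cfg, cell_clones) {
  n_mito <- cfg$n_mito_genes
  n_nuc <- cfg$n_genes - n_mito
  genes <- c(paste0("MT-", seq_len(n_mito)),
             sprintf("G%04d", seq_len(n_nuc)))
  withr::with_seed(cfg$seed + 303L, {
    w <- rlnorm(n_nuc, cfg$gene_meanlog, cfg$gene_sdlog)
    if (!is.null(cfg$planted_de) && !is.null(cfg$planted_weight_quantile)) {
      w[cfg$planted_de$gene] <- quantile(w, cfg$planted_weight_quantile)
    }
    w <- w / sum(w)
    n_cells <- nrow(cell_clones)
    lib <- cfg$libsize_mean * rlnorm(n_cells, 0, cfg$libsize_sdlog)

    group_of <- rep("", n_cells)
    if (!is.null(cfg$de_group_a)) {
      group_of[cell_clones$clone %in% cfg$de_group_a] <- "a"
      group_of[cell_clones$clone %in% cfg$de_group_b] <- "b"
    }
    fold <- matrix(1, nrow = n_nuc, ncol = n_cells)
    planted_genes <- character(0)
    if (!is.null(cfg$planted_de)) {
      for (k in seq_len(nrow(cfg$planted_de))) {
        gi <- cfg$planted_de$gene[k]
        grp <- cfg$planted_de$group[k]
        fold[gi, group_of == grp] <- cfg$planted_de$fold[k]
        planted_genes <- c(planted_genes, sprintf("G%04d", gi))
      }
    }
    mu_nuc <- sweep(w * fold, 2, lib, "*")

    n_high <- round(cfg$frac_high_mito * n_cells)
    high_idx <- sample.int(n_cells, n_high)
    f <- pmin(rbeta(n_cells, cfg$mito_beta_a, cfg$mito_beta_b),
              cfg$mito_trunc)
    f[high_idx] <- runif(n_high, cfg$high_mito_range[1],
                         cfg$high_mito_range[2])
    mito_total <- f / (1 - f) * lib
    mu_mito <- matrix(rep(mito_total / n_mito, each = n_mito), nrow = n_mito)

    cts_nuc <- matrix(rnbinom(n_nuc * n_cells, mu = as.vector(mu_nuc),
                              size = cfg$nb_dispersion), nrow = n_nuc)
    cts_mito <- matrix(stats::rpois(n_mito * n_cells,
                                    lambda = as.vector(mu_mito)),
                       nrow = n_mito)
    counts <- rbind(cts_mito, cts_nuc)
    dimnames(counts) <- list(genes, cell_clones$cell)
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         truth = list(planted_genes = unique(planted_genes),
                      high_mito_cells = cell_clones$cell[high_idx],
                      group_a_cells = cell_clones$cell[group_of == "a"],
                      group_b_cells = cell_clones$cell[group_of == "b"]))
  })
}

#' Simulate long-read molecular bridges
#'
#' A `coverage` fraction of cells emit one correct bridge read (random
#' padding + cell index + spacer + clone barcode + padding, half of them
#' reverse-complemented to exercise strand handling); a `multimap_rate`
#' fraction of covered cells emit an extra read naming a wrong clone, which
#' must force their exclusion.
#'
#' @param cell_clones Tibble `cell`, `clone` (index).
#' @param clone_barcodes Barcode sequence per clone index.
#' @param coverage Fraction of cells covered by a correct bridge.
#' @param multimap_rate Fraction of covered cells contaminated with a
#'   second, wrong clone barcode.
#' @param seed Seed.
#' @return Tibble `read_id`, `sequence`, `cell`, `clone`, `corrupt`
#'   (logical: read names a wrong clone).
#' @export
simulate_bridge_reads <- function(cell_clones, clone_barcodes,
                                  coverage = 0.2, multimap_rate = 0,
                                  seed = 0L) {
  withr::with_seed(seed, {
    n <- nrow(cell_clones)
    covered <- runif(n) < coverage
    rows <- cell_clones[covered, , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(tibble(read_id = character(0), sequence = character(0),
                    cell = character(0), clone = integer(0),
                    corrupt = logical(0)))
    }
    mk_read <- function(cell, bc) {
      s <- paste0(.rand_seq(1, 8), cell, "TTTCTTATAT", bc, .rand_seq(1, 8))
      if (runif(1) < 0.5) {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      s
    }
    good <- tibble(
      read_id = paste0("ccs", seq_len(nrow(rows))),
      sequence = vapply(seq_len(nrow(rows)), function(i)
        mk_read(rows$cell[i], clone_barcodes[rows$clone[i]]), ""),
      cell = rows$cell, clone = rows$clone, corrupt = FALSE)
    contam <- runif(nrow(rows)) < multimap_rate
    bad <- NULL
    if (any(contam)) {
      crows <- rows[contam, , drop = FALSE]
      wrong <- vapply(crows$clone, function(cl)
        sample(setdiff(seq_along(clone_barcodes), cl), 1L), integer(1))
      bad <- tibble(
        read_id = paste0("ccsx", seq_len(nrow(crows))),
        sequence = vapply(seq_len(nrow(crows)), function(i)
          mk_read(crows$cell[i], clone_barcodes[wrong[i]]), ""),
        cell = crows$cell, clone = wrong, corrupt = TRUE)
    }
    bind_rows(good, bad)
  })
}

#' Simulate serial-transplant clone trajectories
#'
#' Passage-to-passage change follows per-clone lognormal fitness, so
#' relative abundances drift monotonically: clones fitter than the
#' population average expand in share, the rest diminish. Truth labels the
#' realized direction (last-passage share above or below the first), the
#' structure the k-means trajectory classifier should recover.
#'
#' @param cfg A [sim_config()] with `n_passages >= 2`.
#' @return List: `trajectories` tibble (`clone`, `passage`, `abundance` in
#'   %), `truth` tibble (`clone`, `class`).
#' @export
simulate_trajectories <- function(cfg) {
  if (cfg$n_passages < 2L) abort("n_passages must be >= 2")
  withr::with_seed(cfg$seed + 404L, {
    base <- rlnorm(cfg$n_clones, cfg$clone_meanlog, cfg$clone_sdlog)
    fitness <- rlnorm(cfg$n_clones, 0, cfg$fitness_sdlog)
    traj <- list()
    w <- base
    for (p in seq_len(cfg$n_passages)) {
      traj[[p]] <- tibble(clone = seq_len(cfg$n_clones), passage = p,
                          abundance = 100 * w / sum(w))
      w <- w * fitness
    }
    tj <- bind_rows(traj)
    first <- tj$abundance[tj$passage == 1L]
    last <- tj$abundance[tj$passage == cfg$n_passages]
    list(trajectories = tj,
         truth = tibble(clone = seq_len(cfg$n_clones),
                        class = ifelse(last > first, "expanding",
                                       "diminishing")))
  })
}

#' Simulate a full cohort to disk
#'
#' Emits everything the pipeline consumes: one barcode FASTQ per
#' mouse-tissue sample, a metadata CSV, an MTX+TSV count matrix channel, a
#' bridge FASTA, a clone-barcode whitelist, and `truth.json` recording the
#' generator's ground truth. Byte-identical across runs with the same
#' config.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list with `paths` and `truth` (in-memory, richer
#'   than the JSON: includes realized read counts).
#' @export
simulate_cohort <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- barcode_spec(cfg$flank5, cfg$flank3, cfg$barcode_len)
  clone_bcs <- simulate_barcodes(cfg$n_clones, cfg$barcode_len,
                                 seed = cfg$seed + 1L)
  props <- simulate_clone_proportions(cfg)

  meta <- props |>
    distinct(.data$sample_id, .data$mouse_id, .data$tissue, .data$scale) |>
    mutate(timepoint_days = 60L, treatment_arm = "none", passage = 1L,
           frac_human_of_mnc = cfg$frac_human_of_mnc,
           frac_gfp_of_human = cfg$frac_gfp_of_human * .data$scale) |>
    select(-"scale")
  if (any(meta$frac_gfp_of_human > 1)) {
    warn("tissue expansion pushed a GFP fraction above 1; capped")
    meta$frac_gfp_of_human <- pmin(meta$frac_gfp_of_human, 1)
  }
  write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)

  fastqs <- character(0)
  true_counts <- list()
  sids <- unique(props$sample_id)
  for (i in seq_along(sids)) {
    sid <- sids[i]
    pr <- props$proportion[props$sample_id == sid]
    reads <- simulate_barcode_reads(pr, clone_bcs, cfg$read_depth, spec,
                                    error_rate = cfg$error_rate,
                                    seed = cfg$seed + 1000L + i)
    fp <- file.path(dir, paste0(sid, ".fastq"))
    write_reads(reads, fp)
    fastqs <- c(fastqs, fp)
    true_counts[[sid]] <- attr(reads, "true_counts")
  }

  cell_clones <- simulate_cell_clones(cfg)
  sc <- simulate_sc_counts(cfg, cell_clones)
  ch_dir <- file.path(dir, "channel1")
  write_mtx_channel(expr_matrix(sc$counts, "channel1"), ch_dir)

  bridges <- simulate_bridge_reads(cell_clones, clone_bcs,
                                   coverage = cfg$bridge_coverage,
                                   multimap_rate = cfg$bridge_multimap_rate,
                                   seed = cfg$seed + 505L)
  write_reads(bridges, file.path(dir, "bridges.fasta"))
  writeLines(clone_bcs, file.path(dir, "clones.txt"))

  trajectories <- NULL
  traj_truth <- NULL
  if (cfg$n_passages >= 2L) {
    tr <- simulate_trajectories(cfg)
    trajectories <- tr$trajectories
    traj_truth <- tr$truth
    write.csv(tr$trajectories, file.path(dir, "trajectories.csv"),
              row.names = FALSE)
  }

  biased <- if (!is.null(cfg$tissue_bias)) {
    mutate(cfg$tissue_bias, barcode = clone_bcs[.data$clone])
  } else NULL

  truth <- list(
    clone_barcodes = clone_bcs,
    proportions = props,
    true_counts = true_counts,
    cell_clones = mutate(cell_clones, barcode = clone_bcs[.data$clone]),
    covered_cells = unique(bridges$cell[!bridges$corrupt]),
    multimapped_cells = unique(bridges$cell[bridges$corrupt]),
    planted_genes = sc$truth$planted_genes,
    high_mito_cells = sc$truth$high_mito_cells,
    group_a_cells = sc$truth$group_a_cells,
    group_b_cells = sc$truth$group_b_cells,
    biased_clones = biased,
    trajectory_truth = traj_truth)
  jsonlite::write_json(
    list(clone_barcodes = clone_bcs,
         planted_genes = sc$truth$planted_genes,
         high_mito_cells = sc$truth$high_mito_cells,
         biased_clones = biased,
         seed = cfg$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(paths = list(dir = dir, meta = file.path(dir, "meta.csv"),
                              fastqs = fastqs, channel = ch_dir,
                              bridges = file.path(dir, "bridges.fasta"),
                              clones = file.path(dir, "clones.txt")),
                 truth = truth, config = cfg))
}
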