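#' Shannon diversity of clonal composition
#'
#' Diversity per sample over detected clones (abundance > 0):
#' H = -sum p_i log_base(p_i) with p_i the within-sample clone proportions.
#' Base 2 (bits) by default. Computed through [vegan::diversity()] and
#' rescaled to the requested base.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @param base Logarithm base; default 2.
#' @return Tibble `sample_id`, `shannon`, `n_clones`.
#' @export
shannon_diversity <- function(abundance, base = 2) {
  abundance |>
    group_by(.data$sample_id) |>
    summarise(shannon = {
      a <- .data$abundance[.data$abundance > 0]
      if (length(a) == 0L) abort("all-zero abundance vector")
      as.numeric(vegan::diversity(a, index = "shannon")) / log(base)
    },
    n_clones = sum(.data$abundance > 0), .groups = "drop")
}

#' Pearson correlation of clonal abundance across samples
#'
#' Computed over the union of clones detected in either sample of each pair
#' (a clone absent from one sample contributes 0 there), on the raw %
#' abundances by default. A zero-variance sample yields `NA` against every
#' other sample.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @param samples Optional sample subset/order; default all samples present.
#' @param log10_scale Correlate `log10(abundance + floor)` instead of raw
#'   percentages.
#' @param floor Pseudo-abundance for the log scale; default 0.001.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_cross_tissue <- function(abundance, samples = NULL,
                                 log10_scale = FALSE, floor = 0.001) {
  m <- abundance_matrix(abundance)
  samples <- samples %||% rownames(m)
  if (length(samples) < 2L) abort("need at least 2 samples")
  missing <- setdiff(samples, rownames(m))
  if (length(missing)) abort(paste0("samples absent from abundance table: ",
                                    paste(missing, collapse = ", ")))
  m <- m[samples, , drop = FALSE]
  if (log10_scale) m <- log10(m + floor)
  r <- suppressWarnings(cor(t(m), method = "pearson"))
  diag(r) <- 1
  r
}

#' Tissue-bias calls against the blood-spleen 99% band
#'
#' Non-biased clones are assumed equally abundant across tissues, so the
#' blood-spleen comparison calibrates how much log2 ratio spread pure
#' sampling produces. The reference distribution is
#' `d = log2((spleen + floor) / (blood + floor))` over clones detected
#' (abundance > `detection_threshold`) in blood or spleen; the band is
#' `mean(d) +/- 2.576 sd(d)` (normal 99% interval) or the empirical
#' 0.5%/99.5% quantiles. Each clone detected in blood or the target tissue
#' is then called from its target-vs-blood log2 ratio: above the band =
#' tissue-biased, below = blood-biased, inside = unbiased.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @param blood_sample,spleen_sample,target_sample Sample ids.
#' @param floor Pseudo-abundance (% of MNC) keeping log ratios finite;
#'   default 0.001 (a tenth of the detection threshold).
#' @param detection_threshold Clone detection cutoff used to choose the
#'   clones entering the reference distribution and the calls; default 0.01.
#' @param band `"normal"` (mean +/- 2.576 sd, default) or `"quantile"`
#'   (empirical 0.5%/99.5%).
#' @return Tibble `clone`, `log2_ratio`, `band_low`, `band_high`, `call`
#'   (`tissue_biased` | `blood_biased` | `unbiased`).
#' @export
tissue_bias <- function(abundance, blood_sample, spleen_sample, target_sample,
                        floor = 0.001, detection_threshold = 0.01,
                        band = c("normal", "quantile")) {
  band <- match.arg(band)
  m <- abundance_matrix(abundance)
  for (s in c(blood_sample, spleen_sample, target_sample)) {
    if (!s %in% rownames(m)) abort(paste0("sample not found: ", s))
  }
  blood <- m[blood_sample, ]; spleen <- m[spleen_sample, ]
  target <- m[target_sample, ]

  ref_clones <- blood > detection_threshold | spleen > detection_threshold
  if (sum(ref_clones) < 3L) {
    abort("need at least 3 clones detected in blood or spleen")
  }
  d <- log2((spleen[ref_clones] + floor) / (blood[ref_clones] + floor))
  if (sd(d) == 0) abort("degenerate reference: blood-spleen ratios constant")
  lims <- if (band == "normal") {
    mean(d) + c(-1, 1) * qnorm(0.995) * sd(d)
  } else {
    unname(quantile(d, c(0.005, 0.995), type = 7))
  }

  call_clones <- blood > detection_threshold | target > detection_threshold
  ratio <- log2((target[call_clones] + floor) / (blood[call_clones] + floor))
  tibble(clone = names(ratio), log2_ratio = unname(ratio),
         band_low = lims[1], band_high = lims[2],
         call = dplyr::case_when(ratio > lims[2] ~ "tissue_biased",
                                 ratio < lims[1] ~ "blood_biased",
                                 TRUE ~ "unbiased"))
}

#' Classify clone trajectories across serial transplants
#'
#' k-means (k = 2, fixed seed, default parameters otherwise) on
#' `log10(mean abundance + floor)` per passage. The cluster whose centroid
#' rises most from first to last passage is labeled `expanding`, the other
#' `diminishing`. If every clone has an identical trajectory the clustering
#' is degenerate; a single-cluster warning is raised and all clones are
#' labeled `diminishing` or `expanding` by the trajectory's own slope.
#'
#' @param trajectories Tibble `clone`, `passage`, `abundance` — the mean
#'   abundance of each clone per transplant generation (averaged over mice
#'   upstream).
#' @param k Number of clusters; default 2.
#' @param seed RNG seed for k-means initialization.
#' @param floor Pseudo-abundance before log10; default 0.001.
#' @return Tibble `clone`, `class` (`expanding` | `diminishing`), plus the
#'   per-passage log10 features; k-means centroids in attribute `centers`.
#' @export
classify_trajectories <- function(trajectories, k = 2L, seed = 0L,
                                  floor = 0.001) {
  wide <- trajectories |>
    arrange(.data$passage) |>
    tidyr::pivot_wider(names_from = "passage", values_from = "abundance")
  feats <- log10(as.matrix(wide[, -1, drop = FALSE]) + floor)
  rownames(feats) <- wide$clone
  if (ncol(feats) < 2L) abort("need at least 2 passages")
  if (nrow(feats) < k) abort("fewer clones than clusters")
  if (nrow(unique(feats)) == 1L) {
    warn("all trajectories identical; single-cluster result")
    slope <- feats[1, ncol(feats)] - feats[1, 1]
    cls <- if (slope > 0) "expanding" else "diminishing"
    return(tibble(clone = rownames(feats), class = cls))
  }
  km <- withr::with_seed(seed, kmeans(feats, centers = k))
  delta <- km$centers[, ncol(feats)] - km$centers[, 1]
  labels <- rep("diminishing", k)
  labels[which.max(delta)] <- "expanding"
  out <- tibble(clone = rownames(feats), class = labels[km$cluster]) |>
    dplyr::bind_cols(as_tibble(feats, .name_repair = ~ paste0("log10_p", .x)))
  attr(out, "centers") <- km$centers
  out
}

#' Log2 fold difference of clonal abundance between treatments
#'
#' `log2((mean_A + floor) / (mean_B + floor))` per clone, means taken over
#' the samples (mice) of each treatment within a tissue.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @param samples_a,samples_b Sample ids of the two treatment arms.
#' @param floor Pseudo-abundance; default 0.001.
#' @return Tibble `clone`, `mean_a`, `mean_b`, `log2fc`.
#' @export
treatment_log2fc <- function(abundance, samples_a, samples_b, floor = 0.001) {
  if (length(samples_a) == 0L || length(samples_b) == 0L) {
    abort("both sample sets must be non-empty")
  }
  m <- abundance_matrix(abundance)
  miss <- setdiff(c(samples_a, samples_b), rownames(m))
  if (length(miss)) abort(paste0("samples absent: ", paste(miss, collapse = ", ")))
  ma <- colMeans(m[samples_a, , drop = FALSE])
  mb <- colMeans(m[samples_b, , drop = FALSE])
  tibble(clone = colnames(m), mean_a = unname(ma), mean_b = unname(mb),
         log2fc = unname(log2((ma + floor) / (mb + floor))))
}

#' Per-clone response differences across treatment arms
#'
#' Two-sided Kruskal-Wallis test of each clone's abundance across treatment
#' arms, Bonferroni-corrected by the number of clones tested. Clones with an
#' arm holding fewer than 2 observations are skipped with a warning.
#'
#' @param abundance Tibble `sample_id`, `barcode`, `abundance`.
#' @param meta Tibble with `sample_id` and `treatment_arm`.
#' @return Tibble `clone`, `h`, `p`, `p_bonferroni` (capped at 1).
#' @export
clone_response_test <- function(abundance, meta) {
  dat <- abundance |>
    inner_join(select(meta, "sample_id", "treatment_arm"), by = "sample_id")
  per_clone <- split(dat, dat$barcode)
  testable <- vapply(per_clone, function(d) {
    sizes <- table(d$treatment_arm)
    length(sizes) >= 2L && all(sizes >= 2L)
  }, logical(1))
  if (any(!testable)) {
    warn(paste0(sum(!testable),
                " clone(s) skipped: an arm has fewer than 2 observations"))
  }
  per_clone <- per_clone[testable]
  if (length(per_clone) == 0L) {
    return(tibble(clone = character(0), h = numeric(0), p = numeric(0),
                  p_bonferroni = numeric(0)))
  }
  res <- purrr::map(per_clone, function(d) {
    if (length(unique(d$abundance)) == 1L) {
      # all observations tied: no evidence of any arm difference
      return(tibble(h = 0, p = 1))
    }
    kt <- kruskal.test(d$abundance, factor(d$treatment_arm))
    tibble(h = unname(kt$statistic), p = unname(kt$p.value))
  })
  out <- bind_rows(res, .id = "clone")
  mutate(out, p_bonferroni = p.adjust(.data$p, method = "bonferroni"))
}
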