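#' Define a clone grouping for differential expression
#'
#' Comparisons contrast cells of clones showing one in-vivo behavior
#' (group A, e.g. bone-marrow-biased, expanding, therapy-responsive) against
#' cells of clones showing another (group B, typically all other clones of
#' the same patient sample).
#'
#' @param group_a,group_b Disjoint, non-empty character vectors of clone
#'   barcodes.
#' @param direction `"a_greater"` tests for genes expressed higher in A,
#'   `"b_greater"` for higher in B. Each direction is a separate one-sided
#'   test family with its own scrambles.
#' @param label Free-text description.
#' @return A `clone_grouping` object.
#' @export
clone_grouping <- function(group_a, group_b,
                           direction = c("a_greater", "b_greater"),
                           label = "") {
  direction <- match.arg(direction)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both clone groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) {
    abort("clone groups must be disjoint")
  }
  structure(list(group_a = unique(group_a), group_b = unique(group_b),
                 direction = direction, label = label),
            class = "clone_grouping")
}

#' Cells belonging to each clone group
#'
#' Cells excluded as multimapped or unmapped in the bridge mapping belong to
#' neither set; so do cells of clones outside both groups.
#'
#' @param map A `cell_clone_map` from [assign_cells()].
#' @param grouping A [clone_grouping()].
#' @return List with character vectors `a` and `b` of cell indexes.
#' @export
cells_for_groups <- function(map, grouping) {
  stopifnot(inherits(map, "cell_clone_map"), inherits(grouping, "clone_grouping"))
  if (nrow(map$assignments) == 0L) abort("map has no assigned cells")
  a <- map$assignments$cell[map$assignments$clone %in% grouping$group_a]
  b <- map$assignments$cell[map$assignments$clone %in% grouping$group_b]
  if (length(a) == 0L || length(b) == 0L) abort("group has no mapped cells")
  list(a = a, b = b)
}

#' Per-gene one-sided Mann-Whitney U tests
#'
#' For every gene, compares expression values of cells in A against cells in
#' B with the Mann-Whitney U statistic (midranks for ties). The one-sided
#' p-value is exact by the null permutation distribution when
#' `min(n_a, n_b) <= 8` and the gene has no ties, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#' A gene whose values are all tied across both groups is degenerate and
#' reported with p = 0.5.
#'
#' @param vals Dense genes-by-cells matrix of expression values (e.g.
#'   [expr_values()]); only columns in `cells_a`/`cells_b` are used.
#' @param cells_a,cells_b Cell index vectors (each of length >= 2).
#' @param direction `"a_greater"` or `"b_greater"`.
#' @param exact_max Largest `min(n_a, n_b)` for which the exact null
#'   distribution is used (no ties); default 8.
#' @return Tibble `gene`, `n_a`, `n_b`, `u`, `p`, `degenerate`. `u` is the
#'   U statistic of group A.
#' @export
mw_test_genes <- function(vals, cells_a, cells_b,
                          direction = c("a_greater", "b_greater"),
                          exact_max = 8L) {
  direction <- match.arg(direction)
  if (length(cells_a) < 2L || length(cells_b) < 2L) {
    abort("need at least 2 cells per group")
  }
  xa <- vals[, cells_a, drop = FALSE]
  xb <- vals[, cells_b, drop = FALSE]
  na <- length(cells_a); nb <- length(cells_b)
  res <- t(vapply(seq_len(nrow(vals)), function(i) {
    .mw_one(xa[i, ], xb[i, ], direction, exact_max)
  }, numeric(3)))
  tibble(gene = rownames(vals), n_a = na, n_b = nb,
         u = res[, 1], p = res[, 2], degenerate = res[, 3] > 0)
}

# returns c(U_a, one-sided p, degenerate flag)
.mw_one <- function(a, b, direction, exact_max) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  # one-sided test on the U of the favored group
  if (direction == "a_greater") {
    u_test <- ua; m <- na; n <- nb
  } else {
    u_test <- na * nb - ua; m <- nb; n <- na
  }
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(c(ua, 0.5, 1))
  if (!has_ties && min(na, nb) <= exact_max) {
    p <- pwilcox(u_test - 1, m, n, lower.tail = FALSE)
  } else {
    z <- (u_test - na * nb / 2 - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
  }
  c(ua, min(p, 1), 0)
}

#' Scramble a cell-to-clone map
#'
#' Produces a permutation null: the assigned cell set and the multiset of
#' clone labels are unchanged, but labels are uniformly permuted across
#' assigned cells under the given seed. Excluded and unmapped sets pass
#' through untouched. Deterministic in `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param map A `cell_clone_map` with at least 2 assigned cells.
#' @param seed Integer seed.
#' @return A scrambled `cell_clone_map`.
#' @export
scramble_map <- function(map, seed) {
  stopifnot(inherits(map, "cell_clone_map"))
  n <- nrow(map$assignments)
  if (n < 2L) abort("need at least 2 assigned cells to scramble")
  perm <- withr::with_seed(seed, sample.int(n))
  out <- map
  out$assignments$clone <- map$assignments$clone[perm]
  out
}

#' False-positive score from scramble comparisons
#'
#' For each gene g, FPS is the number of genes in a scramble dataset whose
#' p-value is at or below g's experimental p-value — the median of that
#' count over the scrambles (the 3rd order statistic of 5) — divided by the
#' number of genes at or below it in the experimental data. The denominator
#' includes g itself, so it is always at least 1. An FPS of 0 means no
#' scramble produced a p-value that small.
#'
#' @param p_experimental Named numeric vector of experimental p-values
#'   (names = genes).
#' @param p_scrambles List of named numeric vectors, one per scramble, over
#'   the same gene set.
#' @return Named numeric vector of FPS values.
#' @export
compute_fps <- function(p_experimental, p_scrambles) {
  genes <- names(p_experimental)
  if (is.null(genes)) abort("p_experimental must be named by gene")
  for (ps in p_scrambles) {
    if (!setequal(names(ps), genes)) {
      abort("scramble and experimental gene sets differ")
    }
  }
  pe <- p_experimental
  # |{g' : p_exp(g') <= p_exp(g)}| including g itself
  denom <- vapply(pe, function(p) sum(pe <= p), numeric(1))
  counts <- vapply(p_scrambles, function(ps) {
    sps <- sort(unname(ps))
    findInterval(pe, sps)  # number of scramble p-values <= p_exp(g)
  }, numeric(length(pe)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  num <- apply(counts, 1, median)
  setNames(num / denom, genes)
}

#' Call significant genes
#'
#' A gene is significant iff both its one-sided p-value and its FPS are
#' strictly below their thresholds (defaults 0.05 and 0.05).
#'
#' @param results Tibble with columns `gene`, `p`, `fps` (extra columns kept).
#' @param alpha_p,alpha_fps Strict thresholds.
#' @return The tibble with a logical `significant` column, sorted by p
#'   ascending with ties broken by gene name.
#' @export
call_significant <- function(results, alpha_p = 0.05, alpha_fps = 0.05) {
  results |>
    mutate(significant = .data$p < alpha_p & .data$fps < alpha_fps) |>
    arrange(.data$p, .data$gene)
}

#' Clone-group differential expression with scramble-based FDR control
#'
#' The full procedure: gather cells per clone group, run the per-gene
#' one-sided Mann-Whitney tests, generate `n_scrambles` permutation-null
#' datasets by scrambling the cell-to-clone map (seeds `seed + 1 ...
#' seed + n_scrambles`), recompute p-values on each, form the
#' false-positive score, and call genes with FPS < `alpha_fps` and
#' p < `alpha_p`.
#'
#' @param expr A normalized [expr_matrix()].
#' @param map A `cell_clone_map`.
#' @param grouping A [clone_grouping()].
#' @param n_scrambles Number of scramble datasets; default 5.
#' @param seed Master seed for scrambles; default 0.
#' @param alpha_p,alpha_fps Significance thresholds (strict).
#' @param scramble_level `"cell"` permutes clone labels across assigned
#'   cells (default); `"clone"` permutes group membership among clones,
#'   keeping each clone's cells together — a coarser null preserving
#'   within-clone correlation.
#' @return A `dge_fps` object; `tidy()` gives the per-gene table, `glance()`
#'   the run summary, `autoplot()` a p-value/FPS panel.
#' @export
dge_fps <- function(expr, map, grouping, n_scrambles = 5L, seed = 0L,
                    alpha_p = 0.05, alpha_fps = 0.05,
                    scramble_level = c("cell", "clone")) {
  scramble_level <- match.arg(scramble_level)
  cells <- cells_for_groups(map, grouping)
  vals <- expr_values(expr, cells = c(cells$a, cells$b))
  exp_res <- mw_test_genes(vals, cells$a, cells$b, grouping$direction)
  p_exp <- setNames(exp_res$p, exp_res$gene)

  p_scr <- lapply(seq_len(n_scrambles), function(s) {
    smap <- switch(scramble_level,
                   cell = scramble_map(map, seed + s),
                   clone = scramble_clone_groups(map, grouping, seed + s))
    scells <- cells_for_groups(smap, grouping)
    sres <- mw_test_genes(vals, scells$a, scells$b, grouping$direction)
    setNames(sres$p, sres$gene)
  })
  fps <- compute_fps(p_exp, p_scr)
  results <- exp_res |>
    mutate(fps = unname(fps[.data$gene])) |>
    call_significant(alpha_p = alpha_p, alpha_fps = alpha_fps)
  structure(list(results = results, grouping = grouping,
                 params = list(n_scrambles = n_scrambles, seed = seed,
                               alpha_p = alpha_p, alpha_fps = alpha_fps,
                               scramble_level = scramble_level,
                               n_a = length(cells$a), n_b = length(cells$b))),
            class = "dge_fps")
}

# clone-level scramble: permute which clones sit in group A vs B vs outside,
# preserving clone cell-blocks; implemented by permuting the clone labels
# themselves (a relabeling of clones), which permutes group membership.
scramble_clone_groups <- function(map, grouping, seed) {
  clones <- unique(map$assignments$clone)
  if (length(clones) < 2L) abort("need at least 2 clones to scramble")
  perm <- withr::with_seed(seed, sample(clones))
  relabel <- setNames(perm, clones)
  out <- map
  out$assignments$clone <- unname(relabel[map$assignments$clone])
  out
}

#' @export
print.dge_fps <- function(x, ...) {
  cat("dge_fps:", x$grouping$label, "(", x$grouping$direction, ")\n")
  cat("  cells:", x$params$n_a, "vs", x$params$n_b,
      "| genes:", nrow(x$results),
      "| significant:", sum(x$results$significant), "\n")
  invisible(x)
}

#' Tidiers for clonotrx result objects
#'
#' `tidy()` returns the per-element table; `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name tidy_clonotrx
NULL

#' @rdname tidy_clonotrx
#' @export
tidy.dge_fps <- function(x, ...) x$results

#' @rdname tidy_clonotrx
#' @export
glance.dge_fps <- function(x, ...) {
  tibble(label = x$grouping$label, direction = x$grouping$direction,
         n_a = x$params$n_a, n_b = x$params$n_b,
         n_genes = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_scrambles = x$params$n_scrambles, seed = x$params$seed,
         alpha_p = x$params$alpha_p, alpha_fps = x$params$alpha_fps)
}

#' Write a DGE result to CSV (plus a run-parameters JSON sidecar)
#'
#' @param x A `dge_fps` object.
#' @param path Output CSV path; parameters go to `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_dge <- function(x, path) {
  utils::write.csv(tidy(x), path, row.names = FALSE)
  jsonlite::write_json(c(x$params, list(label = x$grouping$label,
                                        direction = x$grouping$direction)),
                       paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
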