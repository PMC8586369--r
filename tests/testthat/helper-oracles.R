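# Independent oracles, deliberately naive: enumeration / double loops only.

# One-sided Mann-Whitney p by full enumeration of all C(N, na) group splits
# of the pooled values. direction favors group a ("a_greater") or b.
enum_mw_p <- function(a, b, direction = "a_greater") {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  obs <- if (direction == "a_greater") {
    u_of(seq_len(na))
  } else {
    u_of(na + seq_along(b))
  }
  k <- if (direction == "a_greater") na else length(b)
  splits <- utils::combn(length(pooled), k)
  us <- apply(splits, 2, u_of)
  mean(us >= obs)
}

# FPS by the definition, double loop over genes and scrambles.
brute_fps <- function(p_exp, p_scrambles) {
  genes <- names(p_exp)
  out <- numeric(length(genes))
  for (i in seq_along(genes)) {
    pg <- p_exp[[i]]
    nums <- vapply(p_scrambles, function(ps) sum(ps <= pg), numeric(1))
    denom <- sum(p_exp <= pg)
    out[i] <- median(nums) / denom
  }
  setNames(out, genes)
}

# small deterministic expression container for tests
toy_expr <- function(counts) {
  m <- expr_matrix(counts)
  normalize_expression(m)
}

toy_map <- function(cells, clones, unmapped = character(0),
                    excluded = character(0)) {
  clonotrx:::new_cell_clone_map(
    tibble::tibble(cell = cells, clone = clones,
                   support = rep(1L, length(cells))),
    excluded, unmapped)
}

tiny_spec <- function() barcode_spec("AACCGGTT", "GGTTAACC", 6)

read_with <- function(barcode, spec = tiny_spec(), pre = "AAA", post = "TT") {
  paste0(pre, spec$flank5, barcode, spec$flank3, post)
}
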