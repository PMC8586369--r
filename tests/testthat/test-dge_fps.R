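test_that("group cell lookup respects exclusions and outside clones", {
  map <- toy_map(cells = paste0("c", 1:6),
                 clones = c("B1", "B1", "B1", "B2", "B3", "B3"),
                 excluded = "cx", unmapped = "cu")
  g <- clone_grouping("B1", "B2")
  got <- cells_for_groups(map, g)
  expect_setequal(got$a, c("c1", "c2", "c3"))
  expect_setequal(got$b, "c4")
  # clone B3 in neither group; excluded/unmapped cells nowhere
  expect_false(any(c("c5", "c6", "cx", "cu") %in% c(got$a, got$b)))
  expect_error(cells_for_groups(map, clone_grouping("B1", "B9")),
               "no mapped cells")
  expect_error(clone_grouping("B1", "B1"), "disjoint")
})

test_that("one-sided Mann-Whitney p matches small enumerated cases", {
  vals <- rbind(g1 = c(1, 2, 3, 4))
  colnames(vals) <- paste0("c", 1:4)
  # A = {1,2}, B = {3,4}, direction b_greater -> p = 1/6
  r <- mw_test_genes(vals, c("c1", "c2"), c("c3", "c4"), "b_greater")
  expect_equal(r$p, 1 / 6)
  # A = {5,6,7}, B = {1,2,3}, direction a_greater -> p = 1/20
  vals2 <- rbind(g1 = c(5, 6, 7, 1, 2, 3))
  colnames(vals2) <- paste0("c", 1:6)
  r2 <- mw_test_genes(vals2, paste0("c", 1:3), paste0("c", 4:6), "a_greater")
  expect_equal(r2$p, 1 / 20)
  # identical groups in either direction: p >= 0.5
  vals3 <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  colnames(vals3) <- paste0("c", 1:6)
  r3 <- mw_test_genes(vals3, paste0("c", 1:3), paste0("c", 4:6), "a_greater")
  expect_gte(r3$p, 0.5)
})

test_that("exact p equals full enumeration for all sizes up to n = 10", {
  withr::with_seed(99, {
    for (na in 2:5) {
      for (nb in na:(10 - na)) {
        x <- sample(seq_len(50), na + nb)  # distinct -> no ties
        a <- x[seq_len(na)]; b <- x[na + seq_len(nb)]
        vals <- rbind(g = c(a, b))
        colnames(vals) <- paste0("c", seq_along(x))
        ca <- paste0("c", seq_len(na)); cb <- paste0("c", na + seq_len(nb))
        for (dir in c("a_greater", "b_greater")) {
          got <- mw_test_genes(vals, ca, cb, dir)$p
          expect_equal(got, enum_mw_p(a, b, dir),
                       info = paste(na, nb, dir))
        }
      }
    }
  })
})

test_that("tied and degenerate genes are handled", {
  # all values identical -> degenerate, p = 0.5
  vals <- rbind(g = rep(3, 8))
  colnames(vals) <- paste0("c", 1:8)
  r <- mw_test_genes(vals, paste0("c", 1:4), paste0("c", 5:8), "a_greater")
  expect_equal(r$p, 0.5)
  expect_true(r$degenerate)
  # with ties, the approximation stays close to wilcox.test's
  withr::with_seed(3, {
    a <- rpois(30, 3); b <- rpois(30, 5)
  })
  vals2 <- rbind(g = c(a, b))
  colnames(vals2) <- paste0("c", 1:60)
  got <- mw_test_genes(vals2, paste0("c", 1:30), paste0("c", 31:60),
                       "b_greater")
  ref <- suppressWarnings(
    wilcox.test(b, a, alternative = "greater", correct = TRUE))$p.value
  expect_equal(got$p, ref, tolerance = 1e-10)
})

test_that("scrambling permutes labels, preserves the multiset, and is seeded", {
  map <- toy_map(paste0("c", 1:100),
                 withr::with_seed(4, sample(c("B1", "B2", "B3"), 100,
                                            replace = TRUE)),
                 excluded = "cx", unmapped = c("cu1", "cu2"))
  s1 <- scramble_map(map, 7)
  s2 <- scramble_map(map, 7)
  s3 <- scramble_map(map, 8)
  expect_equal(s1$assignments, s2$assignments)
  expect_false(identical(s1$assignments$clone, s3$assignments$clone))
  expect_equal(sort(s1$assignments$clone), sort(map$assignments$clone))
  expect_equal(s1$assignments$cell, map$assignments$cell)
  expect_equal(s1$excluded_multimapped, map$excluded_multimapped)
  expect_equal(s1$unmapped_cells, map$unmapped_cells)
  expect_error(scramble_map(toy_map("c1", "B1"), 1), "at least 2")
})

test_that("fps matches the brute-force double loop on random instances", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      n <- sample(1:50, 1)
      genes <- paste0("g", seq_len(n))
      pe <- setNames(runif(n), genes)
      ps <- lapply(1:5, function(i) setNames(runif(n), genes))
      expect_identical(compute_fps(pe, ps), brute_fps(pe, ps))
    }
  })
})

test_that("fps identity and extreme cases follow the definition", {
  genes <- paste0("g", 1:4)
  pe <- setNames(c(0.001, 0.5, 0.2, 0.9), genes)
  # scrambles identical to experiment -> fps = 1 everywhere
  same <- lapply(1:5, function(i) pe)
  expect_equal(unname(compute_fps(pe, same)), rep(1, 4))
  # no scramble p as small as the top gene -> fps 0
  pe2 <- setNames(c(0.001, 0.5), c("g1", "g2"))
  ps2 <- lapply(1:5, function(i) setNames(c(0.4, 0.6), c("g1", "g2")))
  expect_equal(compute_fps(pe2, ps2)[["g1"]], 0)
  # deterministic
  expect_identical(compute_fps(pe2, ps2), compute_fps(pe2, ps2))
  expect_error(compute_fps(pe2, list(setNames(0.1, "gX"))), "differ")
})

test_that("significance calls are strict on both thresholds", {
  tbl <- tibble::tibble(gene = c("a", "b", "c"),
                        p = c(0.04, 0.05, 0.01),
                        fps = c(0.04, 0.0, 0.06))
  got <- call_significant(tbl)
  expect_equal(got$significant[got$gene == "a"], TRUE)
  expect_equal(got$significant[got$gene == "b"], FALSE)  # p not < 0.05
  expect_equal(got$significant[got$gene == "c"], FALSE)  # fps not < 0.05
  expect_equal(got$gene, c("c", "a", "b"))  # sorted by p, ties by name
})

test_that("planted fold changes are recovered and nulls stay quiet", {
  cfg <- sim_config(n_clones = 4, n_cells = 300, n_genes = 200,
                    planted_de = tibble::tibble(gene = c(20L, 40L),
                                                group = "a", fold = 8),
                    de_group_a = 1:2, de_group_b = 3:4, seed = 61)
  cc <- simulate_cell_clones(cfg)
  sc <- simulate_sc_counts(cfg, cc)
  m <- normalize_expression(filter_genes(expr_matrix(sc$counts),
                                         min_cell_frac = 0.01))
  map <- toy_map(cc$cell, paste0("B", cc$clone))
  d <- dge_fps(m, map, clone_grouping(c("B1", "B2"), c("B3", "B4"),
                                      "a_greater"),
               seed = 100)
  sig <- tidy(d)$gene[tidy(d)$significant]
  expect_true(all(sc$truth$planted_genes %in% sig))
  expect_lte(length(setdiff(sig, sc$truth$planted_genes)), 3L)
  g <- glance(d)
  expect_equal(g$n_a, length(sc$truth$group_a_cells))
  expect_equal(g$n_significant, length(sig))
})

test_that("both one-sided families recover up- and down-regulated genes", {
  cfg <- sim_config(n_clones = 4, n_cells = 400, n_genes = 150,
                    planted_de = tibble::tibble(gene = c(30L, 60L),
                                                group = c("a", "b"),
                                                fold = 8),
                    de_group_a = 1:2, de_group_b = 3:4, seed = 71)
  cc <- simulate_cell_clones(cfg)
  sc <- simulate_sc_counts(cfg, cc)
  m <- normalize_expression(filter_genes(expr_matrix(sc$counts),
                                         min_cell_frac = 0.01))
  map <- toy_map(cc$cell, paste0("B", cc$clone))
  up <- dge_fps(m, map, clone_grouping(c("B1", "B2"), c("B3", "B4"),
                                       "a_greater"), seed = 1)
  dn <- dge_fps(m, map, clone_grouping(c("B1", "B2"), c("B3", "B4"),
                                       "b_greater"), seed = 2)
  expect_true("G0030" %in% tidy(up)$gene[tidy(up)$significant])
  expect_true("G0060" %in% tidy(dn)$gene[tidy(dn)$significant])
})
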