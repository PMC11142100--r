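test_that("orientation reverses A3S(+) and A5S(-) and is an involution", {
  expect_equal(orientation_sign("A3S", "+"), -1)
  expect_equal(orientation_sign("A3S", "-"), 1)
  expect_equal(orientation_sign("A5S", "-"), -1)
  expect_equal(orientation_sign("A5S", "+"), 1)
  for (t in c("CASSETTE", "IR", "MXE", "COMPOSITE")) {
    expect_equal(orientation_sign(t, "+"), 1)
    expect_equal(orientation_sign(t, "-"), 1)
  }
  set.seed(4)
  types <- sample(c("CASSETTE", "A3S", "A5S", "MXE"), 20, replace = TRUE)
  strands <- sample(c("+", "-"), 20, replace = TRUE)
  raw <- runif(20, -1, 1)
  s <- orientation_sign(types, strands)
  expect_equal(raw * s * s, raw)
})

test_that("first delta PSI applies the strand-aware sign by hand cases", {
  mk <- function(as_type, strand, raw) {
    ann <- toy_annotation("e", as_type = as_type, strand = strand,
                          inclusion_junction =
                            if (as_type %in% c("CASSETTE", "IR")) 1L else NA_integer_)
    res <- tibble::tibble(event_id = "e", delta_first = raw)
    first_delta_psi(res, ann)
  }
  expect_equal(mk("A3S", "+", 0.30), -0.30)
  expect_equal(mk("CASSETTE", "+", 0.20), 0.20)
  expect_equal(mk("A5S", "-", -0.15), 0.15)
  expect_error(first_delta_psi(tibble::tibble(event_id = "nope",
                                              delta_first = 0.1),
                               toy_annotation("e")), "not in annotations")
})

test_that("uniqueness index sums only significant oriented deltas", {
  # 4 cells, focal mean 0.9 vs 0.1, 0.1, 0.5: index = 0.8 + 0.8 + 0.4
  ann <- toy_annotation("ev")
  comp <- tibble::tibble(
    as_type = "CASSETTE", event_id = "ev", cell_a = "F",
    cell_b = c("c1", "c2", "c3"),
    delta_psi = c(0.8, 0.8, 0.4), delta_first = c(0.8, 0.8, 0.4),
    p_value = 0.001, q_value = 0.004, significant = TRUE,
    n_a = 4L, n_b = 4L
  )
  attr(comp, "cell_types") <- c("F", "c1", "c2", "c3")
  rec <- uniqueness_index(comp, ann, "ev", "F")
  expect_equal(rec$index, 2.0)
  expect_equal(rec$n_significant, 3L)
  expect_equal(rec$n_compared, 3L)

  none <- comp
  none$significant <- FALSE
  expect_equal(uniqueness_index(none, ann, "ev", "F")$index, 0)
  expect_error(uniqueness_index(comp, ann, "ev", "Q"), "absent")
})

test_that("uniqueness index equals brute-force summation on random sets", {
  for (seed in 1:10) {
    rcs <- random_comparison_set(n_cells = sample(3:6, 1),
                                 n_events = 4, seed = 1000 + seed)
    for (ev in rcs$annotations$event_id) {
      for (ct in rcs$cells) {
        got <- uniqueness_index(rcs$comparisons, rcs$annotations, ev, ct)
        want <- brute_force_index(rcs$comparisons, rcs$annotations, ev, ct)
        expect_equal(got$index, want$index)
        expect_equal(got$n_significant, want$n_significant)
        # bound: |index| <= n_significant <= N - 1
        expect_lte(abs(got$index), got$n_significant + 1e-12)
        expect_lte(got$n_significant, length(rcs$cells) - 1)
      }
    }
  }
})

test_that("uniqueness table ranks deterministically and matches records", {
  rcs <- random_comparison_set(n_cells = 5, n_events = 6, seed = 77)
  tab <- uniqueness_table(rcs$comparisons, rcs$annotations)
  expect_equal(nrow(tab), 6 * 5)  # one record per (event, cell)
  expect_true(all(diff(abs(tab$index)) <= 1e-12))  # magnitude-sorted
  for (i in sample(nrow(tab), 10)) {
    want <- brute_force_index(rcs$comparisons, rcs$annotations,
                              tab$feature_id[i], tab$focal_cell[i])
    expect_equal(tab$index[i], want$index)
  }

  two <- tibble::tibble(
    as_type = "A3S", event_id = c("up", "down"), cell_a = "F",
    cell_b = "o", delta_psi = c(-3.1, 4.0), delta_first = c(-3.1, 4.0),
    p_value = 0, q_value = 0, significant = TRUE, n_a = 2L, n_b = 2L
  )
  ann2 <- dplyr::bind_rows(
    toy_annotation("up", as_type = "A3S", strand = "+",
                   inclusion_junction = NA_integer_),
    toy_annotation("down", as_type = "A3S", strand = "+",
                   inclusion_junction = NA_integer_)
  )
  attr(two, "cell_types") <- c("F", "o")
  asc <- uniqueness_table(two, ann2, sort = "ascending")
  expect_equal(asc$index[1], -4.0)  # most uniquely downstream first

  zero <- two
  zero$significant <- FALSE
  z <- uniqueness_table(zero, ann2)
  expect_equal(z$index, rep(0, 4))
  expect_equal(z$feature_id, c("down", "down", "up", "up"))
})

test_that("expression test computes CPM fold change with strict gates", {
  same <- expression_pair_test(c(100, 110, 90), c(100, 110, 90))
  expect_equal(same$log2_fold_change, 0)
  expect_false(same$significant)

  de <- expression_pair_test(c(400, 440, 420), c(10, 9, 11))
  expect_equal(de$log2_fold_change, log2(421) - log2(11), tolerance = 1e-12)
  expect_gt(abs(de$log2_fold_change), 2)
  expect_true(de$significant)

  # |log2FC| of 1.5 fails the effect gate no matter the p-value
  weak <- expression_pair_test(c(283, 283, 283), c(100, 100, 100))
  expect_lt(abs(weak$log2_fold_change), 2)
  expect_equal(weak$p_value, 0)  # zero variance, different means
  expect_false(weak$significant)

  expect_error(expression_pair_test(c(1, 2), c(3, 4),
                                    lib_sizes_a = c(0, 10),
                                    lib_sizes_b = c(10, 10)),
               "zero library")
})

test_that("expression uniqueness sums significant log2 fold changes", {
  # gene 16-fold up in focal vs all 3 others: index = 3 * log2(16) = 12;
  # a large balancing gene keeps every library the same size so the CPM
  # ratio equals the count ratio
  genes <- paste0("g", 1:6)
  counts <- matrix(100, nrow = 6, ncol = 8,
                   dimnames = list(genes, paste0("s", 1:8)))
  smap <- sample_map(paste0("s", 1:8), rep(c("F", "o1", "o2", "o3"), each = 2))
  counts["g6", ] <- 10000
  counts["g1", 1:2] <- 1600
  counts["g6", 1:2] <- 10000 - 1500
  expect_equal(length(unique(colSums(counts))), 1L)
  res <- run_expression_pairs(counts, smap)
  rec <- expression_uniqueness(res, "g1", "F")
  expect_equal(rec$n_significant, 3L)
  expect_equal(rec$index,
               sum(res$log2_fold_change[res$gene_id == "g1" &
                                          res$cell_a == "F" & res$significant]))
  expect_gt(rec$index, 0.85 * 12)  # CPM pseudocount shrinks log2(16) slightly
  expect_lte(rec$index, 12)

  null_rec <- expression_uniqueness(res, "g2", "F")
  expect_equal(null_rec$index, 0)
  expect_error(expression_uniqueness(res, "nope", "F"), "absent")

  # gene-subset filter caps the records per cell
  sub <- expression_uniqueness_table(res, genes = c("g1", "g2"))
  expect_lte(max(table(sub$focal_cell)), 2)
})
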