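test_that("differential counts per pair match an independent recount", {
  sim <- small_sim(seed = 14)
  comp <- run_all_pairs(sim$psi)
  counts <- count_differential(comp)
  expect_true(all(counts$n_significant >= 0))
  expect_false(any(counts$cell_a == counts$cell_b))
  # oracle: recount straight off the comparison rows with table()
  sig <- comp[comp$significant, ]
  for (i in sample(nrow(counts), 20)) {
    want <- sum(sig$as_type == counts$as_type[i] &
                  sig$cell_a == counts$cell_a[i] &
                  sig$cell_b == counts$cell_b[i])
    expect_equal(counts$n_significant[i], want)
  }
  expect_equal(sum(counts$n_significant), nrow(sig))
  # invariant to row shuffling of the comparison set
  shuffled <- comp[sample(nrow(comp)), ]
  attr(shuffled, "pairs") <- attr(comp, "pairs")
  c2 <- count_differential(shuffled)
  expect_equal(dplyr::arrange(c2, as_type, cell_a, cell_b),
               dplyr::arrange(counts, as_type, cell_a, cell_b))
})

test_that("global totals require five significant comparisons", {
  mk_comp <- function(n_sig) {
    tibble::tibble(
      as_type = "IR", event_id = "ev", cell_a = "F",
      cell_b = paste0("o", seq_len(8)),
      delta_psi = 0.5, delta_first = 0.5, p_value = 0.001, q_value = 0.001,
      significant = seq_len(8) <= n_sig, n_a = 4L, n_b = 4L
    )
  }
  ann <- toy_annotation("ev", as_type = "IR")
  in6 <- global_totals(mk_comp(6), ann)
  expect_equal(in6$n_events[in6$as_type == "IR"], 1L)
  expect_equal(in6$n_genes[in6$as_type == "IR"], 1L)
  out4 <- global_totals(mk_comp(4), ann)
  expect_equal(out4$n_events[out4$as_type == "IR"], 0L)

  # a simulation where planted IR events dominate shows IR on top
  cfg <- sim_config(n_cell_types = 8, n_replicates = 4,
                    events_per_type = c(CASSETTE = 5, IR = 5),
                    planted_fraction = 0, seed = 55)
  sim <- simulate_splicing(cfg)
  # plant strong IR-only differences by hand: first two IR events split the
  # cells into two deterministic groups
  long <- sim$counts$counts
  ir_ids <- sim$annotations$event_id[sim$annotations$as_type == "IR"][1:2]
  hi <- sim$sample_map$sample_id[
    sim$sample_map$cell_type %in% paste0("CT0", 1:4)]
  for (ev in ir_ids) {
    sel <- long$event_id == ev
    long$count[sel] <- ifelse(long$sample_id[sel] %in% hi,
                              ifelse(long$subjunction_index[sel] == 1, 180L, 20L),
                              ifelse(long$subjunction_index[sel] == 1, 20L, 180L))
  }
  psi <- compute_psi(junction_counts(long, sim$sample_map), sim$annotations)
  totals <- global_totals(run_all_pairs(psi), sim$annotations)
  expect_equal(totals$as_type[which.max(totals$n_events)], "IR")
  expect_equal(max(totals$fraction_events), 1)
})

test_that("splice-type correlations report adjusted R-squared", {
  pairs <- tidyr::crossing(cell_a = paste0("c", 1:5), cell_b = paste0("c", 1:5))
  pairs <- pairs[pairs$cell_a < pairs$cell_b, ]  # m = 10 unordered pairs
  x <- c(3, 7, 1, 9, 4, 6, 2, 8, 5, 10)
  mk <- function(type, v) {
    tibble::tibble(as_type = type, cell_a = pairs$cell_a,
                   cell_b = pairs$cell_b, n_significant = as.integer(v))
  }
  exact <- dplyr::bind_rows(mk("CASSETTE", x), mk("IR", x))
  r_exact <- splice_type_correlation(exact)
  expect_equal(r_exact["CASSETTE", "IR"], 1)

  # hand-sized case against the closed form 1 - (1 - r^2)(m - 1)/(m - 2)
  y <- c(4, 6, 2, 9, 3, 7, 1, 9, 6, 8)
  hand <- dplyr::bind_rows(mk("CASSETTE", x), mk("IR", y))
  m <- 10
  r2 <- stats::cor(x, y)^2
  expect_equal(splice_type_correlation(hand)["CASSETTE", "IR"],
               1 - (1 - r2) * (m - 1) / (m - 2), tolerance = 1e-12)

  # independent categories decorrelate at large m (seed-pinned)
  set.seed(31)
  big_pairs <- tibble::tibble(cell_a = sprintf("a%03d", 1:500),
                              cell_b = sprintf("b%03d", 1:500))
  noise <- dplyr::bind_rows(
    tibble::tibble(as_type = "CASSETTE", big_pairs,
                   n_significant = rpois(500, 5)),
    tibble::tibble(as_type = "IR", big_pairs,
                   n_significant = rpois(500, 5)))
  expect_lt(abs(splice_type_correlation(noise)["CASSETTE", "IR"]), 0.1)

  const <- dplyr::bind_rows(mk("CASSETTE", rep(2, 10)), mk("IR", y))
  expect_warning(rc <- splice_type_correlation(const), "constant")
  expect_equal(rc["IR", "CASSETTE"], 0)
})

test_that("outlier cells are flagged per splicing type by robust z", {
  cells <- paste0("c", 1:12)
  pairs <- enumerate_pairs(cells)
  mk <- function(type, per_cell) {
    tibble::tibble(as_type = type, cell_a = pairs$cell_a,
                   cell_b = pairs$cell_b,
                   n_significant = as.integer(per_cell[pairs$cell_a]))
  }
  base <- stats::setNames(rep(2L, 12), cells)
  loaded <- base
  loaded["c7"] <- 40L
  counts <- dplyr::bind_rows(mk("A3S", loaded), mk("CASSETTE", base))
  a3 <- outlier_cells(counts, "A3S")
  expect_equal(a3$cell_type[a3$outlier], "c7")
  cas <- outlier_cells(counts, "CASSETTE")
  expect_false(any(cas$outlier))
  expect_error(outlier_cells(counts, "MXE"), "no counts")
})

test_that("directional bias counts positive nonzero indices", {
  uniq <- tibble::tibble(
    as_type = "A3S", feature_id = paste0("e", 1:8), focal_cell = "OLL",
    index = c(0.5, 0.3, -0.2, 0.8, 0.1, 0.4, 0, 0),
    n_significant = 1L, n_compared = 4L
  )
  expect_equal(directional_bias(uniq, "OLL", "A3S"), 5 / 6)
  allpos <- uniq
  allpos$index <- abs(allpos$index)
  expect_equal(directional_bias(allpos, "OLL"), 1)
  expect_true(is.na(directional_bias(uniq, "ASK")))

  # mirrored data (PSI -> 1 - PSI) flips the bias exactly
  sim <- small_sim(seed = 101)
  mirrored <- new_psi_table(1 - sim$psi$psi, sim$sample_map,
                            sim$annotations, first = 1 - sim$psi$first)
  u1 <- uniqueness_table(run_all_pairs(sim$psi), sim$annotations)
  u2 <- uniqueness_table(run_all_pairs(mirrored), sim$annotations)
  for (ct in c("CT01", "CT04")) {
    b1 <- directional_bias(u1, ct)
    b2 <- directional_bias(u2, ct)
    if (!is.na(b1) && !is.na(b2)) expect_equal(b2, 1 - b1)
  }
})

test_that("usage mega matrix averages replicates and keeps NA missing", {
  smap <- toy_map("A", reps = 3)
  counts <- junction_counts(tibble::tibble(
    event_id = "ev1",
    subjunction_index = rep(1:2, each = 3),
    sample_id = rep(smap$sample_id, 2),
    count = as.integer(c(70, 80, 90, 30, 20, 10))
  ), smap)
  psi <- compute_psi(counts, toy_annotation())
  usage <- usage_mega_matrix(psi)
  expect_equal(usage$usage, 0.8)
  expect_equal(usage$n_replicates, 3L)

  sim <- small_sim(seed = 61)
  long <- sim$counts$counts
  # undetect one event entirely in CT02
  off <- sim$sample_map$sample_id[sim$sample_map$cell_type == "CT02"]
  long$count[long$event_id == "CASSETTE_001" & long$sample_id %in% off] <- 0L
  psi2 <- compute_psi(junction_counts(long, sim$sample_map), sim$annotations)
  um <- usage_mega_matrix(psi2)
  cell2 <- um[um$event_id == "CASSETTE_001" & um$cell_type == "CT02", ]
  expect_true(is.na(cell2$usage))
  expect_true(all(um$usage >= 0 & um$usage <= 1, na.rm = TRUE))
  # every event detected anywhere appears for every cell type
  expect_equal(nrow(um),
               length(unique(um$event_id)) *
                 length(unique(sim$sample_map$cell_type)))

  # replicate permutation leaves the means unchanged
  perm <- sample(ncol(psi2$psi))
  psi_perm <- new_psi_table(psi2$psi[, perm], sim$sample_map,
                            sim$annotations, first = psi2$first[, perm])
  um2 <- usage_mega_matrix(psi_perm)
  expect_equal(dplyr::arrange(um2, event_id, cell_type)$usage,
               dplyr::arrange(um, event_id, cell_type)$usage)
})
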