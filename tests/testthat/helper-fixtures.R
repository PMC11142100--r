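# fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdirs

toy_map <- function(cells, reps = 2) {
  sample_map(
    sample_id = unlist(lapply(cells, function(ct) paste0(ct, "_r", seq_len(reps)))),
    cell_type = rep(cells, each = reps)
  )
}

toy_annotation <- function(event_id = "ev1", as_type = "CASSETTE",
                           strand = "+", starts = c(100L, 200L),
                           ends = c(600L, 700L),
                           inclusion_junction = if (as_type %in% c("CASSETTE", "IR")) 1L else NA_integer_,
                           gene_id = paste0("g_", event_id)) {
  event_annotations(event_id = event_id, gene_id = gene_id, chrom = "chrI",
                    strand = strand, as_type = as_type,
                    starts = list(starts), ends = list(ends),
                    inclusion_junction = inclusion_junction)
}

# one two-junction event whose per-cell PSI is deterministic:
# inclusion reads = depth * psi, skipping reads = depth * (1 - psi)
deterministic_counts <- function(psi_by_cell, reps = 4, depth = 200,
                                 annotation = toy_annotation()) {
  cells <- names(psi_by_cell)
  smap <- toy_map(cells, reps)
  incl <- round(depth * psi_by_cell[smap$cell_type])
  rows <- tibble::tibble(
    event_id = annotation$event_id,
    subjunction_index = rep(1:2, each = nrow(smap)),
    sample_id = rep(smap$sample_id, 2),
    count = as.integer(c(incl, depth - incl))
  )
  if (!is.na(annotation$inclusion_junction) &&
      annotation$inclusion_junction == 2L) {
    rows$count <- as.integer(c(depth - incl, incl))
  }
  list(counts = junction_counts(rows, smap), annotations = annotation,
       sample_map = smap)
}

# random antisymmetric comparison set over n_cells and n_events, for oracle
# checks; delta_first is the raw (unoriented) first-junction delta
random_comparison_set <- function(n_cells, n_events, seed,
                                  types = c("CASSETTE", "A3S", "A5S", "MXE")) {
  set.seed(seed)
  cells <- paste0("c", seq_len(n_cells))
  ann <- event_annotations(
    event_id = paste0("e", seq_len(n_events)),
    gene_id = paste0("g", seq_len(n_events)),
    chrom = "chrI",
    strand = sample(c("+", "-"), n_events, replace = TRUE),
    as_type = sample(types, n_events, replace = TRUE),
    starts = replicate(n_events, c(100L, 200L), simplify = FALSE),
    ends = replicate(n_events, c(500L, 600L), simplify = FALSE),
    inclusion_junction = 1L
  )
  half <- tidyr::crossing(event_id = ann$event_id,
                          enumerate_pairs(cells))
  half <- half[half$cell_a < half$cell_b, ]
  half$delta_first <- round(stats::runif(nrow(half), -1, 1), 3)
  half$significant <- stats::runif(nrow(half)) < 0.4
  # drop some pairs entirely to emulate undetected events
  half <- half[stats::runif(nrow(half)) > 0.2, ]
  mirror <- half
  names(mirror)[names(mirror) == "cell_a"] <- "tmp"
  names(mirror)[names(mirror) == "cell_b"] <- "cell_a"
  names(mirror)[names(mirror) == "tmp"] <- "cell_b"
  mirror$delta_first <- -mirror$delta_first
  comp <- dplyr::bind_rows(half, mirror)
  comp$as_type <- ann$as_type[match(comp$event_id, ann$event_id)]
  comp$delta_psi <- comp$delta_first
  comp$p_value <- ifelse(comp$significant, 0.001, 0.5)
  comp$q_value <- comp$p_value
  attr(comp, "cell_types") <- cells
  list(comparisons = comp, annotations = ann, cells = cells)
}

# independent oracle: plain double loop with the orientation rule restated
brute_force_index <- function(comparisons, annotations, feature, focal) {
  total <- 0
  n_sig <- 0
  for (i in seq_len(nrow(comparisons))) {
    row <- comparisons[i, ]
    if (row$event_id != feature || row$cell_a != focal) next
    if (!row$significant) next
    idx <- which(annotations$event_id == row$event_id)
    type <- annotations$as_type[idx]
    strand <- annotations$strand[idx]
    flip <- (type == "A3S" && strand == "+") ||
      (type == "A5S" && strand == "-")
    total <- total + if (flip) -row$delta_first else row$delta_first
    n_sig <- n_sig + 1
  }
  list(index = total, n_significant = n_sig)
}

small_sim <- function(seed = 42, n_cell_types = 5, reps = 3) {
  cfg <- sim_config(
    n_cell_types = n_cell_types, n_replicates = reps,
    events_per_type = c(CASSETTE = 3, MXE = 3, A5S = 3, A3S = 3, IR = 3,
                        COMPOSITE = 3),
    planted_fraction = 0.1, seed = seed
  )
  sim <- simulate_splicing(cfg)
  psi <- compute_psi(sim$counts, sim$annotations)
  c(sim, list(psi = psi, config = cfg))
}
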