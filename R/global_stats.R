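#' Count significant events per ordered cell pair and splicing type
#'
#' Per-comparison counting keeps a minimum threshold of a single event,
#' since one event can be called at most once within one comparison.
#'
#' @param comparisons Comparison tibble from [run_all_pairs()].
#' @return Tibble (`as_type`, `cell_a`, `cell_b`, `n_significant`) covering
#'   every enumerated pair and every splicing type seen, zeros included.
#' @export
count_differential <- function(comparisons) {
  pairs <- attr(comparisons, "pairs") %||%
    dplyr::distinct(comparisons[c("cell_a", "cell_b")])
  types <- sort(unique(comparisons$as_type))
  tab <- dplyr::summarise(
    dplyr::group_by(comparisons, .data$as_type, .data$cell_a, .data$cell_b),
    n_significant = sum(.data$significant), .groups = "drop"
  )
  grid <- tidyr::crossing(as_type = types, pairs)
  out <- dplyr::left_join(grid, tab, by = c("as_type", "cell_a", "cell_b"))
  out$n_significant[is.na(out$n_significant)] <- 0L
  out$n_significant <- as.integer(out$n_significant)
  out
}

#' Global totals of differentially spliced events and genes
#'
#' An event enters the global totals only when it is called significant in
#' at least `global_min_comparisons` pairwise comparisons; a gene counts as
#' uniquely spliced when at least one of its events qualifies. Fractions
#' are of qualifying events across splicing types.
#'
#' @param comparisons Comparison tibble.
#' @param annotations Annotation tibble (for gene ids).
#' @param config Thresholds from [as_config()].
#' @return Tibble (`as_type`, `n_events`, `n_genes`, `fraction_events`).
#' @export
global_totals <- function(comparisons, annotations,
                          config = as_config()) {
  per_event <- dplyr::summarise(
    dplyr::group_by(comparisons, .data$as_type, .data$event_id),
    n_calls = sum(.data$significant), .groups = "drop"
  )
  per_event <- per_event[per_event$n_calls >= config$global_min_comparisons, ]
  per_event$gene_id <- annotations$gene_id[match(per_event$event_id,
                                                 annotations$event_id)]
  out <- dplyr::summarise(
    dplyr::group_by(per_event, .data$as_type),
    n_events = dplyr::n(),
    n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop"
  )
  all_types <- sort(unique(comparisons$as_type))
  out <- tidyr::complete(out, as_type = all_types,
                         fill = list(n_events = 0L, n_genes = 0L))
  total <- sum(out$n_events)
  out$fraction_events <- if (total > 0) out$n_events / total else NA_real_
  out
}

#' Correlation of differential counts between splicing types
#'
#' For every pair of categories (splicing types, plus gene expression when
#' supplied), regresses the per-cell-pair significant-event counts of one
#' category on the other by ordinary least squares and reports adjusted
#' R-squared. Each unordered cell pair contributes one observation.
#'
#' @param counts Count tibble from [count_differential()].
#' @param expr_counts Optional tibble (`cell_a`, `cell_b`,
#'   `n_significant`) of differential-expression counts per ordered pair.
#' @return Symmetric matrix of adjusted R-squared values.
#' @export
splice_type_correlation <- function(counts, expr_counts = NULL) {
  unordered <- counts[counts$cell_a < counts$cell_b, ]
  wide <- tidyr::pivot_wider(unordered, names_from = "as_type",
                             values_from = "n_significant",
                             values_fill = 0L)
  if (!is.null(expr_counts)) {
    e <- expr_counts[expr_counts$cell_a < expr_counts$cell_b, ]
    e <- dplyr::rename(e, expression = "n_significant")
    wide <- dplyr::left_join(wide, e, by = c("cell_a", "cell_b"))
    wide$expression[is.na(wide$expression)] <- 0L
  }
  cats <- setdiff(names(wide), c("cell_a", "cell_b"))
  m <- nrow(wide)
  if (m < 3) stop("need at least 3 cell-pair observations")
  out <- matrix(NA_real_, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (i in cats) {
    for (j in cats) {
      if (i == j) {
        out[i, j] <- 1
        next
      }
      x <- wide[[j]]
      y <- wide[[i]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant counts for ", if (stats::sd(x) == 0) j else i,
                "; adjusted R-squared reported as 0")
        out[i, j] <- 0
        next
      }
      out[i, j] <- summary(stats::lm(y ~ x))$adj.r.squared
    }
  }
  out
}

#' Per-cell totals of significant events with robust outlier flags
#'
#' Totals each cell type's significant events over its comparisons against
#' all other cells, then scores cells by a robust z
#' (total minus median, over the median absolute deviation) and flags
#' |z| > 3.5.
#'
#' @param counts Count tibble from [count_differential()].
#' @param as_type Splicing class to total.
#' @return Tibble (`cell_type`, `n_events`, `robust_z`, `outlier`).
#' @export
outlier_cells <- function(counts, as_type) {
  sel <- counts[counts$as_type == as_type, ]
  if (nrow(sel) == 0) stop("no counts for splicing type ", as_type)
  tot <- dplyr::summarise(
    dplyr::group_by(sel, cell_type = .data$cell_a),
    n_events = sum(.data$n_significant), .groups = "drop"
  )
  med <- stats::median(tot$n_events)
  s <- stats::mad(tot$n_events)
  z <- if (s > 0) {
    (tot$n_events - med) / s
  } else {
    ifelse(tot$n_events == med, 0, sign(tot$n_events - med) * Inf)
  }
  tibble::tibble(cell_type = tot$cell_type, n_events = tot$n_events,
                 robust_z = z, outlier = abs(z) > 3.5)
}

#' Directional splice-site bias of a focal cell
#'
#' Fraction of a cell's nonzero uniqueness records with a positive index
#' (positive = upstream choice after orientation). Undefined (`NA`) when
#' the cell has no nonzero records.
#'
#' @param uniq Uniqueness table from [uniqueness_table()].
#' @param focal_cell Cell type.
#' @param as_type Optional splicing-class restriction.
#' @return Fraction in [0,1], or `NA` when undefined.
#' @export
directional_bias <- function(uniq, focal_cell, as_type = NULL) {
  rows <- uniq[uniq$focal_cell == focal_cell, ]
  if (!is.null(as_type)) rows <- rows[rows$as_type %in% as_type, ]
  nz <- rows$index[rows$index != 0]
  if (length(nz) == 0) return(NA_real_)
  mean(nz > 0)
}

#' Replicate-averaged junction-usage matrix
#'
#' Per splicing type, the representative-junction usage of every event is
#' averaged across each cell type's detected replicates; cells failing the
#' detection filter are missing (`NA`), never zero. Events detected in any
#' cell appear in every cell's rows.
#'
#' @param psi A `psi_table`.
#' @return Tibble (`as_type`, `event_id`, `cell_type`, `usage`,
#'   `n_replicates`).
#' @export
usage_mega_matrix <- function(psi) {
  smap <- psi$sample_map
  cells <- unique(smap$cell_type)
  det <- detected_by_cell(psi)
  means <- cell_type_means(psi$psi, smap)
  nrep <- vapply(cells, function(ct) {
    cols <- smap$sample_id[smap$cell_type == ct]
    rowSums(!is.na(psi$psi[, cols, drop = FALSE]))
  }, numeric(nrow(psi$psi)))
  if (nrow(psi$psi) == 1) {
    nrep <- matrix(nrep, nrow = 1, dimnames = list(rownames(psi$psi), cells))
  }
  ann <- psi$annotations
  events <- rownames(psi$psi)
  out <- tidyr::crossing(event_id = events, cell_type = cells)
  out$usage <- ifelse(det[cbind(out$event_id, out$cell_type)],
                      means[cbind(out$event_id, out$cell_type)], NA_real_)
  out$n_replicates <- as.integer(nrep[cbind(out$event_id, out$cell_type)])
  out$as_type <- if (is.null(ann)) {
    NA_character_
  } else {
    ann$as_type[match(out$event_id, ann$event_id)]
  }
  keep <- events[rowSums(det) > 0]
  out <- out[out$event_id %in% keep, ]
  out[c("as_type", "event_id", "cell_type", "usage", "n_replicates")]
}

#' Write one wide usage matrix TSV per splicing type
#'
#' @param usage Tibble from [usage_mega_matrix()].
#' @param dir Output directory; files are named `megamatrix_<type>.tsv`.
#' @return Paths of the written files, invisibly.
#' @export
write_mega_matrices <- function(usage, dir) {
  paths <- character(0)
  for (t in sort(unique(usage$as_type))) {
    sel <- usage[usage$as_type == t, c("event_id", "cell_type", "usage")]
    sel$usage <- ifelse(is.na(sel$usage), NA_character_,
                        sprintf("%.6f", sel$usage))
    wide <- tidyr::pivot_wider(sel, names_from = "cell_type",
                               values_from = "usage")
    wide <- dplyr::arrange(wide, .data$event_id)
    p <- file.path(dir, paste0("megamatrix_", t, ".tsv"))
    readr::write_tsv(wide, p, na = "", progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
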