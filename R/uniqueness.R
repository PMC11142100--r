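#' Orientation sign for first-junction deltas
#'
#' "Upstream" is defined in transcript orientation. For alternative 3'
#' splice sites on the plus strand and alternative 5' splice sites on the
#' minus strand, the most-upstream *genomic* sub-junction is the
#' transcript-downstream choice, so their deltas are sign-reversed during
#' summation; all other classes keep their sign.
#'
#' @param as_type Event class vector.
#' @param strand `"+"` or `"-"` per event.
#' @return Vector of +1 / -1.
#' @export
orientation_sign <- function(as_type, strand) {
  strand <- normalize_strand(strand)
  ifelse((as_type == "A3S" & strand == "+") |
           (as_type == "A5S" & strand == "-"), -1, 1)
}

#' Oriented first delta PSI of comparison results
#'
#' Takes the delta of the event's most-upstream sub-junction (smallest
#' genomic start, ties by end) and applies the strand-aware orientation so
#' that a positive value always means more upstream / more included usage
#' in `cell_a`.
#'
#' @param result One or more rows of a comparison tibble.
#' @param annotations Annotation tibble covering the events.
#' @return Numeric vector of oriented first deltas.
#' @export
first_delta_psi <- function(result, annotations) {
  idx <- match(result$event_id, annotations$event_id)
  if (anyNA(idx)) {
    stop("event(s) not in annotations: ",
         paste(unique(result$event_id[is.na(idx)]), collapse = ", "))
  }
  result$delta_first * orientation_sign(annotations$as_type[idx],
                                        annotations$strand[idx])
}

comparison_cells <- function(comparisons) {
  attr(comparisons, "cell_types") %||%
    unique(c(comparisons$cell_a, comparisons$cell_b))
}

#' Uniqueness index of one event in one focal cell type
#'
#' Sums the oriented first delta PSI of the focal cell against every other
#' cell type, keeping only significant comparisons; non-significant or
#' undetected pairs contribute exactly zero. With N cell types the index is
#' bounded by +/-(N-1): the maximum is reached when the event is fully
#' included in the focal cell and fully excluded everywhere else.
#'
#' @param comparisons Comparison tibble from [run_all_pairs()].
#' @param annotations Annotation tibble.
#' @param feature Event id.
#' @param focal_cell Cell type whose specificity is scored.
#' @return One-row tibble: `feature_id`, `focal_cell`, `as_type`, `index`,
#'   `n_significant`, `n_compared`.
#' @export
uniqueness_index <- function(comparisons, annotations, feature, focal_cell) {
  if (!focal_cell %in% comparison_cells(comparisons)) {
    stop("focal cell absent from comparison set: ", focal_cell)
  }
  rows <- comparisons[comparisons$cell_a == focal_cell &
                        comparisons$event_id == feature, ]
  oriented <- if (nrow(rows) > 0) first_delta_psi(rows, annotations) else numeric(0)
  idx <- match(feature, annotations$event_id)
  tibble::tibble(
    feature_id = feature,
    focal_cell = focal_cell,
    as_type = if (is.na(idx)) NA_character_ else annotations$as_type[idx],
    index = sum(oriented[rows$significant]),
    n_significant = sum(rows$significant),
    n_compared = nrow(rows)
  )
}

#' Uniqueness table over all events and focal cells
#'
#' One record per (event, focal cell), including zero records for cells
#' where the event was never compared, with a deterministic ranking.
#'
#' @param comparisons Comparison tibble from [run_all_pairs()].
#' @param annotations Annotation tibble.
#' @param as_type Optional restriction to one splicing class.
#' @param sort `"magnitude"` (|index| descending), `"ascending"` (most
#'   uniquely negative first) or `"descending"`; ties break by
#'   (|index| descending, feature_id, focal_cell).
#' @return Tibble of uniqueness records.
#' @export
uniqueness_table <- function(comparisons, annotations, as_type = NULL,
                             sort = c("magnitude", "ascending",
                                      "descending")) {
  sort <- match.arg(sort)
  cells <- comparison_cells(comparisons)
  res <- comparisons
  if (!is.null(as_type)) res <- res[res$as_type %in% as_type, ]
  if (nrow(res) > 0) {
    res$oriented <- first_delta_psi(res, annotations)
    tab <- dplyr::summarise(
      dplyr::group_by(res, feature_id = .data$event_id,
                      focal_cell = .data$cell_a),
      index = sum(.data$oriented[.data$significant]),
      n_significant = sum(.data$significant),
      n_compared = dplyr::n(), .groups = "drop"
    )
  } else {
    tab <- tibble::tibble(feature_id = character(), focal_cell = character(),
                          index = numeric(), n_significant = integer(),
                          n_compared = integer())
  }
  tab <- tidyr::complete(
    tab, feature_id = unique(tab$feature_id),
    focal_cell = cells,
    fill = list(index = 0, n_significant = 0L, n_compared = 0L)
  )
  tab$as_type <- annotations$as_type[match(tab$feature_id,
                                           annotations$event_id)]
  tab <- tab[c("as_type", "feature_id", "focal_cell", "index",
               "n_significant", "n_compared")]
  switch(sort,
    magnitude = dplyr::arrange(tab, dplyr::desc(abs(.data$index)),
                               .data$feature_id, .data$focal_cell),
    ascending = dplyr::arrange(tab, .data$index, .data$feature_id,
                               .data$focal_cell),
    descending = dplyr::arrange(tab, dplyr::desc(.data$index),
                                .data$feature_id, .data$focal_cell)
  )
}

#' Two-group differential-expression test for one gene
#'
#' Counts are converted to counts per million (CPM); the fold change is
#' `log2((mean CPM_a + 1) / (mean CPM_b + 1))` and the p-value comes from a
#' Welch test on log2(CPM + 1). A call is significant when p < `expr_p_max`
#' and |log2FC| > `expr_lfc_min`.
#'
#' @param counts_a,counts_b Non-negative replicate counts for one gene.
#' @param lib_sizes_a,lib_sizes_b Library sizes per replicate; when omitted
#'   the counts are taken to be CPM already.
#' @param config Thresholds from [as_config()].
#' @return One-row tibble: `log2_fold_change`, `p_value`, `significant`.
#' @export
expression_pair_test <- function(counts_a, counts_b, lib_sizes_a = NULL,
                                 lib_sizes_b = NULL,
                                 config = as_config()) {
  to_cpm <- function(x, lib) {
    if (is.null(lib)) return(as.numeric(x))
    if (any(lib <= 0)) stop("zero library size")
    1e6 * x / lib
  }
  cpm_a <- to_cpm(counts_a, lib_sizes_a)
  cpm_b <- to_cpm(counts_b, lib_sizes_b)
  lfc <- log2((mean(cpm_a) + 1) / (mean(cpm_b) + 1))
  la <- log2(cpm_a + 1)
  lb <- log2(cpm_b + 1)
  va <- if (length(la) > 1) stats::var(la) else 0
  vb <- if (length(lb) > 1) stats::var(lb) else 0
  p <- if (va + vb <= 0) {
    if (abs(mean(la) - mean(lb)) > 1e-12) 0 else 1
  } else {
    welch_p(mean(la), mean(lb), va, vb, length(la), length(lb))
  }
  tibble::tibble(
    log2_fold_change = lfc, p_value = p,
    significant = p < config$expr_p_max & abs(lfc) > config$expr_lfc_min
  )
}

#' Differential expression across all ordered cell-type pairs
#'
#' @param counts Gene-by-sample matrix of non-negative counts with gene ids
#'   as rownames and sample ids as colnames.
#' @param sample_map Sample-map tibble covering the columns.
#' @param config Thresholds from [as_config()].
#' @return Tibble of per-gene results for every ordered pair, with a
#'   `cell_types` attribute.
#' @export
run_expression_pairs <- function(counts, sample_map,
                                 config = as_config()) {
  if (is.null(rownames(counts))) stop("counts needs gene_id rownames")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  lcpm <- log2(cpm + 1)
  cells <- unique(sample_map$cell_type)
  pairs <- enumerate_pairs(cells)
  cols <- lapply(cells, function(ct) {
    match(sample_map$sample_id[sample_map$cell_type == ct], colnames(counts))
  })
  names(cols) <- cells
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ia <- cols[[pairs$cell_a[i]]]
    ib <- cols[[pairs$cell_b[i]]]
    ca <- cpm[, ia, drop = FALSE]
    cb <- cpm[, ib, drop = FALSE]
    la <- lcpm[, ia, drop = FALSE]
    lb <- lcpm[, ib, drop = FALSE]
    lfc <- log2((rowMeans(ca) + 1) / (rowMeans(cb) + 1))
    ma <- rowMeans(la)
    mb <- rowMeans(lb)
    va <- row_vars(la)
    vb <- row_vars(lb)
    p <- welch_p(ma, mb, va, vb, length(ia), length(ib))
    zv <- (va + vb) <= 0
    p[zv] <- ifelse(abs(ma[zv] - mb[zv]) > 1e-12, 0, 1)
    res[[i]] <- tibble::tibble(
      gene_id = rownames(counts), cell_a = pairs$cell_a[i],
      cell_b = pairs$cell_b[i], log2_fold_change = unname(lfc),
      p_value = unname(p),
      significant = p < config$expr_p_max &
        abs(lfc) > config$expr_lfc_min
    )
  }
  out <- dplyr::bind_rows(res)
  attr(out, "cell_types") <- cells
  out
}

#' Expression uniqueness index for one gene in one focal cell
#'
#' Sums the log2 fold changes of the focal cell's significant comparisons
#' against all other cell types.
#'
#' @param expr_results Tibble from [run_expression_pairs()].
#' @param gene Gene id.
#' @param focal_cell Cell type.
#' @return One-row uniqueness record tibble.
#' @export
expression_uniqueness <- function(expr_results, gene, focal_cell) {
  if (!gene %in% expr_results$gene_id) stop("gene absent: ", gene)
  cells <- attr(expr_results, "cell_types") %||%
    unique(c(expr_results$cell_a, expr_results$cell_b))
  if (!focal_cell %in% cells) {
    stop("focal cell absent from expression results: ", focal_cell)
  }
  rows <- expr_results[expr_results$cell_a == focal_cell &
                         expr_results$gene_id == gene, ]
  tibble::tibble(
    feature_id = gene, focal_cell = focal_cell,
    index = sum(rows$log2_fold_change[rows$significant]),
    n_significant = sum(rows$significant),
    n_compared = nrow(rows)
  )
}

#' Expression uniqueness table over all genes and focal cells
#'
#' @param expr_results Tibble from [run_expression_pairs()].
#' @param genes Optional gene subset (e.g. a curated RNA-binding-protein
#'   list) applied before ranking.
#' @param sort As in [uniqueness_table()].
#' @return Tibble of uniqueness records ranked deterministically.
#' @export
expression_uniqueness_table <- function(expr_results, genes = NULL,
                                        sort = c("magnitude", "ascending",
                                                 "descending")) {
  sort <- match.arg(sort)
  res <- expr_results
  if (!is.null(genes)) res <- res[res$gene_id %in% genes, ]
  tab <- dplyr::summarise(
    dplyr::group_by(res, feature_id = .data$gene_id,
                    focal_cell = .data$cell_a),
    index = sum(.data$log2_fold_change[.data$significant]),
    n_significant = sum(.data$significant),
    n_compared = dplyr::n(), .groups = "drop"
  )
  switch(sort,
    magnitude = dplyr::arrange(tab, dplyr::desc(abs(.data$index)),
                               .data$feature_id, .data$focal_cell),
    ascending = dplyr::arrange(tab, .data$index, .data$feature_id,
                               .data$focal_cell),
    descending = dplyr::arrange(tab, dplyr::desc(.data$index),
                                .data$feature_id, .data$focal_cell)
  )
}
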