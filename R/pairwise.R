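#' Enumerate every ordered pair of cell types
#'
#' The pairwise framework runs each cell type against every other cell type
#' in both orders, so N cell types give N(N-1) ordered comparisons.
#'
#' @param cell_types Character vector of distinct cell-type labels.
#' @return Tibble with columns `cell_a`, `cell_b`.
#' @export
enumerate_pairs <- function(cell_types) {
  cell_types <- unique(cell_types)
  if (length(cell_types) < 2) stop("need at least 2 cell types")
  grid <- expand.grid(cell_b = cell_types, cell_a = cell_types,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$cell_a != grid$cell_b, c("cell_a", "cell_b")]
  ord <- order(match(grid$cell_a, cell_types), match(grid$cell_b, cell_types))
  tibble::as_tibble(grid[ord, ])
}

#' Two-group location test on replicate PSI values
#'
#' The default is Welch's t-test on the replicate values. An exact
#' permutation test on the difference of means (all label reassignments,
#' two-sided) is available as `method = "permutation"` for small groups;
#' note its smallest attainable p-value is 2 / choose(n, n_a), which with
#' typical 4-vs-4 replicate designs (2/70) is too coarse to survive
#' FDR adjustment across an event family, so the pairwise engine uses
#' Welch throughout. Under either method, when both groups have zero
#' variance the p-value is 0 if the means differ and 1 if they are equal.
#'
#' @param psis_a,psis_b Numeric replicate values (fractions); `NA` dropped.
#' @param method `"welch"` (default) or `"permutation"` (exact enumeration;
#'   requires at most 12 non-missing replicates in total).
#' @return A single p-value.
#' @export
two_group_test <- function(psis_a, psis_b,
                           method = c("welch", "permutation")) {
  method <- match.arg(method)
  a <- psis_a[!is.na(psis_a)]
  b <- psis_b[!is.na(psis_b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  d <- mean(a) - mean(b)
  va <- if (length(a) > 1) stats::var(a) else 0
  vb <- if (length(b) > 1) stats::var(b) else 0
  if (va + vb <= 0) return(if (abs(d) > 1e-12) 0 else 1)
  if (method == "permutation") {
    n <- length(a) + length(b)
    if (n > 12) stop("exact permutation limited to 12 replicates in total")
    x <- c(a, b)
    combs <- utils::combn(n, length(a))
    diffs <- apply(combs, 2, function(i) mean(x[i]) - mean(x[-i]))
    return(mean(abs(diffs) >= abs(d) - 1e-12))
  }
  welch_p(mean(a), mean(b), va, vb, length(a), length(b))
}

# vectorized Welch p; single-replicate groups contribute zero variance
welch_p <- function(ma, mb, va, vb, na, nb) {
  n <- length(ma)
  na <- rep_len(na, n)
  nb <- rep_len(nb, n)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  den <- (va / na)^2 / pmax(na - 1, 1) * (na > 1) +
    (vb / nb)^2 / pmax(nb - 1, 1) * (nb > 1)
  df <- se2^2 / den
  2 * stats::pt(-abs(tstat), df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p_values Numeric vector of p-values in [0,1].
#' @return Vector of q-values, same order as the input.
#' @export
adjust_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

# shared precomputation for the pairwise engine
pair_prep <- function(psi) {
  smap <- psi$sample_map
  cells <- unique(smap$cell_type)
  cols <- lapply(cells, function(ct) which(smap$cell_type == ct))
  names(cols) <- cells
  ann <- psi$annotations
  as_type <- if (is.null(ann)) {
    stats::setNames(rep("CASSETTE", nrow(psi$psi)), rownames(psi$psi))
  } else {
    stats::setNames(ann$as_type[match(rownames(psi$psi), ann$event_id)],
                    rownames(psi$psi))
  }
  list(P = psi$psi, F = psi$first, cols = cols, cells = cells,
       detect = detected_by_cell(psi), as_type = as_type)
}

compare_pair_core <- function(prep, cell_a, cell_b, config,
                              events = NULL) {
  keep <- prep$detect[, cell_a] & prep$detect[, cell_b]
  if (!is.null(events)) keep <- keep & rownames(prep$P) %in% events
  ids <- rownames(prep$P)[keep]
  if (length(ids) == 0) {
    return(tibble::tibble(as_type = character(), event_id = character(),
                          cell_a = character(), cell_b = character(),
                          delta_psi = numeric(), delta_first = numeric(),
                          p_value = numeric(), q_value = numeric(),
                          significant = logical(), n_a = integer(),
                          n_b = integer()))
  }
  A <- prep$P[ids, prep$cols[[cell_a]], drop = FALSE]
  B <- prep$P[ids, prep$cols[[cell_b]], drop = FALSE]
  FA <- prep$F[ids, prep$cols[[cell_a]], drop = FALSE]
  FB <- prep$F[ids, prep$cols[[cell_b]], drop = FALSE]
  n_a <- rowSums(!is.na(A))
  n_b <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE)
  mb <- rowMeans(B, na.rm = TRUE)
  delta <- ma - mb
  delta_first <- rowMeans(FA, na.rm = TRUE) - rowMeans(FB, na.rm = TRUE)
  va <- row_vars(A)
  vb <- row_vars(B)

  p <- rep(NA_real_, length(ids))
  zv <- (va + vb) <= 0
  p[zv] <- ifelse(abs(delta[zv]) > 1e-12, 0, 1)
  if (any(!zv)) {
    p[!zv] <- welch_p(ma[!zv], mb[!zv], va[!zv], vb[!zv],
                      n_a[!zv], n_b[!zv])
  }

  as_type <- unname(prep$as_type[ids])
  q <- stats::ave(p, as_type, FUN = adjust_fdr)
  tibble::tibble(
    as_type = as_type, event_id = ids, cell_a = cell_a, cell_b = cell_b,
    delta_psi = unname(delta), delta_first = unname(delta_first),
    p_value = unname(p), q_value = unname(q),
    significant = abs(delta) > config$delta_psi_min &
      p < config$p_max & q < config$q_max,
    n_a = as.integer(n_a), n_b = as.integer(n_b)
  )
}

#' Differential splicing between one ordered pair of cell types
#'
#' Events must pass the detection filter in both cell types; each surviving
#' event gets a delta PSI (mean PSI in `cell_a` minus mean PSI in `cell_b`,
#' representative junction), a p-value from [two_group_test()], and a BH
#' q-value computed within this comparison's events of the same splicing
#' type. A call is significant when |delta PSI| > `delta_psi_min` and both
#' p and q pass their thresholds.
#'
#' @param psi A `psi_table` (with sample map and annotations).
#' @param cell_a,cell_b Cell-type labels (ordered; delta is a minus b).
#' @param events Optional restriction to a set of event ids.
#' @param config Thresholds from [as_config()].
#' @return Tibble of comparison results, one row per event.
#' @export
compare_pair <- function(psi, cell_a, cell_b, events = NULL,
                         config = as_config()) {
  for (ct in c(cell_a, cell_b)) {
    if (sum(psi$sample_map$cell_type == ct) == 0) {
      stop("cell type with zero samples: ", ct)
    }
  }
  compare_pair_core(pair_prep(psi), cell_a, cell_b, config, events)
}

#' Differential splicing across all ordered pairs of cell types
#'
#' Runs [compare_pair()] for every ordered pair of cell types in the sample
#' map (N cell types give N(N-1) comparisons) and binds the results.
#'
#' @param psi A `psi_table`.
#' @param config Thresholds from [as_config()].
#' @param events Optional restriction to a set of event ids.
#' @return Tibble of comparison results with attributes `pairs` (the ordered
#'   pair enumeration) and `cell_types`.
#' @export
run_all_pairs <- function(psi, config = as_config(), events = NULL) {
  cells <- unique(psi$sample_map$cell_type)
  if (length(cells) < 2) stop("need at least 2 cell types")
  pairs <- enumerate_pairs(cells)
  prep <- pair_prep(psi)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res[[i]] <- compare_pair_core(prep, pairs$cell_a[i], pairs$cell_b[i],
                                  config, events)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "pairs") <- pairs
  attr(out, "cell_types") <- cells
  out
}
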