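#' PSI table
#'
#' Container for per-sample junction usage. `psi` holds the
#' representative-junction usage (the event's PSI) as an events-by-samples
#' matrix with `NA` meaning undetected; `first` holds the usage of the
#' event's most-upstream sub-junction (smallest genomic start, ties broken
#' by end), which is the quantity summed by the uniqueness index.
#'
#' @param psi Numeric matrix, events x samples, values in [0,1] or `NA`.
#' @param sample_map Sample-map tibble covering the matrix columns.
#' @param annotations Optional annotation tibble; used to derive `first`
#'   from `psi` for two-junction events when `first` is not supplied.
#' @param first Optional matrix like `psi` for the first sub-junction.
#' @param usage Optional long tibble of full per-sub-junction usage.
#' @return A `psi_table` object.
#' @export
new_psi_table <- function(psi, sample_map, annotations = NULL, first = NULL,
                          usage = NULL) {
  if (is.null(rownames(psi))) stop("psi matrix needs event_id rownames")
  miss <- setdiff(colnames(psi), sample_map$sample_id)
  if (length(miss) > 0) {
    stop("psi sample(s) not in sample map: ", paste(miss, collapse = ", "))
  }
  if (is.null(first)) {
    first <- psi
    if (!is.null(annotations)) {
      ann <- annotations[match(rownames(psi), annotations$event_id), ]
      r <- representative_indices(ann)
      f <- first_junction_indices(ann)
      k <- lengths(ann$starts)
      flip <- which(!is.na(r) & r != f & k == 2)
      if (length(flip) > 0) first[flip, ] <- 1 - psi[flip, ]
      unknown <- which(!is.na(r) & r != f & k > 2)
      if (length(unknown) > 0) first[unknown, ] <- NA_real_
    }
  }
  structure(list(psi = psi, first = first, usage = usage,
                 sample_map = sample_map, annotations = annotations),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat("psi_table:", nrow(x$psi), "events x", ncol(x$psi), "samples (",
      length(unique(x$sample_map$cell_type)), "cell types )\n")
  invisible(x)
}

# representative sub-junction per annotation row (vectorized over events):
# CASSETTE/IR use the flagged inclusion junction; A5S/A3S/MXE use the
# transcript-upstream junction (smallest start on "+", largest on "-");
# COMPOSITE uses the most-upstream genomic coordinate regardless of strand
representative_indices <- function(annotations) {
  vapply(seq_len(nrow(annotations)), function(i) {
    type <- annotations$as_type[i]
    s <- annotations$starts[[i]]
    e <- annotations$ends[[i]]
    if (type %in% c("CASSETTE", "IR")) {
      incl <- annotations$inclusion_junction[i]
      if (is.na(incl)) {
        stop("no inclusion junction flagged for ", type, " event ",
             annotations$event_id[i])
      }
      return(as.integer(incl))
    }
    if (type %in% c("A5S", "A3S", "MXE")) {
      if (annotations$strand[i] == "+") {
        return(order(s, e)[1])
      }
      return(order(-s, -e)[1])
    }
    order(s, e)[1]  # COMPOSITE
  }, integer(1))
}

first_junction_indices <- function(annotations) {
  vapply(seq_len(nrow(annotations)),
         function(i) order(annotations$starts[[i]], annotations$ends[[i]])[1],
         integer(1))
}

#' Select the representative sub-junction of one event
#'
#' The representative junction carries the event's PSI: the inclusion
#' (retention) junction for cassette exons and retained introns, and the
#' transcript-upstream junction for alternative 5'/3' splice sites and
#' mutually exclusive exons ("upstream" follows the gene's 5' to 3'
#' direction, so it is the smallest genomic start on the plus strand and the
#' largest on the minus strand). Composite events use the most-upstream
#' genomic sub-junction.
#'
#' @param event One-row annotation tibble.
#' @return Integer sub-junction index (1-based).
#' @export
select_representative_junction <- function(event) {
  stopifnot(nrow(event) == 1)
  representative_indices(event)
}

#' Compute per-sample PSI from junction counts
#'
#' Per event and sample, each sub-junction's usage is its read count divided
#' by the event's total reads over all annotated sub-junctions. A sample is
#' undetected for an event (PSI `NA`) when that total is below
#' `junction_min_reads`.
#'
#' @param counts A `junction_counts` object.
#' @param annotations Annotation tibble covering every event in `counts`.
#' @param config Thresholds from [as_config()].
#' @return A `psi_table`.
#' @export
compute_psi <- function(counts, annotations, config = as_config()) {
  stopifnot(inherits(counts, "junction_counts"))
  long <- counts$counts
  unknown <- setdiff(unique(long$event_id), annotations$event_id)
  if (length(unknown) > 0) {
    stop("event(s) missing from annotations: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  events <- annotations$event_id[annotations$event_id %in% long$event_id]
  ann <- annotations[match(events, annotations$event_id), ]
  r_idx <- stats::setNames(representative_indices(ann), events)
  f_idx <- stats::setNames(first_junction_indices(ann), events)
  smap <- counts$sample_map

  totals <- dplyr::summarise(
    dplyr::group_by(long, .data$event_id, .data$sample_id),
    total = sum(.data$count), .groups = "drop"
  )
  key_counts <- function(idx) {
    sel <- long[long$subjunction_index == idx[long$event_id], ]
    dplyr::select(sel, "event_id", "sample_id", sel_count = "count")
  }
  grid <- totals
  grid <- dplyr::left_join(grid, key_counts(r_idx),
                           by = c("event_id", "sample_id"))
  names(grid)[names(grid) == "sel_count"] <- "rep_count"
  grid <- dplyr::left_join(grid, key_counts(f_idx),
                           by = c("event_id", "sample_id"))
  names(grid)[names(grid) == "sel_count"] <- "first_count"
  grid$rep_count[is.na(grid$rep_count)] <- 0L
  grid$first_count[is.na(grid$first_count)] <- 0L
  grid$detected <- grid$total >= config$junction_min_reads
  grid$psi <- ifelse(grid$detected, grid$rep_count / grid$total, NA_real_)
  grid$first <- ifelse(grid$detected, grid$first_count / grid$total,
                       NA_real_)

  to_matrix <- function(value) {
    m <- matrix(NA_real_, nrow = length(events),
                ncol = nrow(smap),
                dimnames = list(events, smap$sample_id))
    m[cbind(grid$event_id, grid$sample_id)] <- value
    m
  }
  usage <- dplyr::left_join(long, totals, by = c("event_id", "sample_id"))
  usage <- usage[usage$total >= config$junction_min_reads, ]
  usage$usage <- usage$count / usage$total
  usage <- dplyr::select(usage, "event_id", "subjunction_index",
                         "sample_id", "usage")

  new_psi_table(psi = to_matrix(grid$psi), sample_map = smap,
                annotations = ann, first = to_matrix(grid$first),
                usage = tibble::as_tibble(usage))
}

# events x cell-types logical matrix of the (n - 1)-replicate detection rule
detected_by_cell <- function(psi) {
  cells <- unique(psi$sample_map$cell_type)
  m <- vapply(cells, function(ct) {
    cols <- psi$sample_map$sample_id[psi$sample_map$cell_type == ct]
    n <- length(cols)
    rowSums(!is.na(psi$psi[, cols, drop = FALSE])) >= n - 1
  }, logical(nrow(psi$psi)))
  if (nrow(psi$psi) == 1) m <- matrix(m, nrow = 1, dimnames = list(rownames(psi$psi), cells))
  m
}

#' Events detected in a cell type
#'
#' An event is detected in a cell type when it is quantified (enough
#' junction reads) in at least n - 1 of the cell's n replicates.
#'
#' @param psi A `psi_table`.
#' @param cell_type Cell-type label.
#' @return Character vector of detected event ids.
#' @export
detection_filter <- function(psi, cell_type) {
  if (!cell_type %in% psi$sample_map$cell_type) {
    stop("unknown cell type: ", cell_type)
  }
  cols <- psi$sample_map$sample_id[psi$sample_map$cell_type == cell_type]
  n <- length(cols)
  det <- rowSums(!is.na(psi$psi[, cols, drop = FALSE])) >= n - 1
  rownames(psi$psi)[det]
}

#' Events with alternative (intermediate) usage
#'
#' An event counts as alternatively spliced when its replicate-mean PSI in
#' at least one cell type lies in the closed band [0.10, 0.90].
#'
#' @param psi A `psi_table`.
#' @return Character vector of event ids.
#' @export
classify_alternative <- function(psi) {
  means <- cell_type_means(psi$psi, psi$sample_map)
  alt <- apply(means, 1, function(x) {
    any(!is.na(x) & x >= 0.10 & x <= 0.90)
  })
  rownames(psi$psi)[alt]
}

# replicate means per cell type; NA when no replicate is detected
cell_type_means <- function(m, smap) {
  cells <- unique(smap$cell_type)
  out <- vapply(cells, function(ct) {
    cols <- smap$sample_id[smap$cell_type == ct]
    mu <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    mu
  }, numeric(nrow(m)))
  if (nrow(m) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(m), cells))
  out
}

#' Drop alternative splice-site events with more than two coordinates
#'
#' Alternative 3'/5' splice-site events offering more than two candidate
#' coordinates are removed; all other event classes pass through unchanged.
#'
#' @param annotations Annotation tibble.
#' @return Filtered annotation tibble.
#' @export
filter_multi_coordinate <- function(annotations) {
  drop <- annotations$as_type %in% c("A3S", "A5S") &
    lengths(annotations$starts) > 2
  annotations[!drop, ]
}
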