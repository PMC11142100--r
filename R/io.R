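#' Build or validate a sample-to-cell-type map
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param cell_type Character vector of cell-type labels, one per sample.
#' @param replicate_index Positive integer replicate number within cell type;
#'   derived automatically when omitted.
#' @return A tibble with columns `sample_id`, `cell_type`, `replicate_index`.
#' @export
sample_map <- function(sample_id, cell_type, replicate_index = NULL) {
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample_id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (length(sample_id) != length(cell_type)) {
    stop("sample_id and cell_type must have equal length")
  }
  if (is.null(replicate_index)) {
    replicate_index <- stats::ave(seq_along(sample_id), cell_type,
                                  FUN = seq_along)
  }
  if (any(replicate_index < 1 | replicate_index != as.integer(replicate_index))) {
    stop("replicate_index must be positive integers")
  }
  map <- tibble::tibble(
    sample_id = as.character(sample_id),
    cell_type = as.character(cell_type),
    replicate_index = as.integer(replicate_index)
  )
  singles <- names(which(table(map$cell_type) < 2))
  if (length(singles) > 0) {
    warning("cell type(s) with a single replicate: ",
            paste(singles, collapse = ", "))
  }
  map
}

#' Read a sample map from TSV
#'
#' Expects columns `sample_id`, `cell_type` and optionally `replicate_index`.
#'
#' @param path Path to a TSV file.
#' @return A sample-map tibble (see [sample_map()]).
#' @export
read_sample_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("sample_id", "cell_type")
  if (!all(req %in% names(tab))) {
    stop("sample map must have columns: ", paste(req, collapse = ", "))
  }
  rep_idx <- if ("replicate_index" %in% names(tab)) {
    as.integer(tab$replicate_index)
  } else {
    NULL
  }
  sample_map(tab$sample_id, tab$cell_type, rep_idx)
}

#' @rdname read_sample_map
#' @param map A sample-map tibble.
#' @export
write_sample_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Splicing-event annotations
#'
#' Constructs the annotation table defining each alternative-splicing event:
#' its class, strand and the ordered genomic spans of its sub-junctions
#' (1-based inclusive coordinates). For cassette and intron-retention events
#' `inclusion_junction` names the sub-junction (1-based index into the
#' coordinate lists) whose usage is the inclusion/retention signal.
#'
#' @param event_id,gene_id,chrom Character vectors.
#' @param strand `"+"` or `"-"` per event.
#' @param as_type One of `CASSETTE`, `MXE`, `A5S`, `A3S`, `IR`, `COMPOSITE`.
#' @param starts,ends Lists of integer vectors, one per event, equal lengths,
#'   `starts <= ends` elementwise, at least two sub-junctions per event.
#' @param inclusion_junction Integer index of the inclusion junction, or `NA`
#'   for classes where it does not apply.
#' @return A tibble with list columns `starts` and `ends`.
#' @export
event_annotations <- function(event_id, gene_id, chrom, strand, as_type,
                              starts, ends, inclusion_junction = NA_integer_) {
  strand <- normalize_strand(strand)
  check_as_type(as_type)
  ann <- tibble::tibble(
    event_id = as.character(event_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    as_type = as.character(as_type),
    starts = lapply(starts, as.integer),
    ends = lapply(ends, as.integer),
    inclusion_junction = as.integer(rep_len(inclusion_junction,
                                            length(event_id)))
  )
  if (anyDuplicated(ann$event_id)) stop("duplicated event_id in annotations")
  n_s <- lengths(ann$starts)
  n_e <- lengths(ann$ends)
  if (any(n_s != n_e)) stop("starts and ends must have equal lengths per event")
  if (any(n_s < 2)) {
    stop("events with fewer than 2 sub-junctions: ",
         paste(ann$event_id[n_s < 2], collapse = ", "))
  }
  ok <- mapply(function(s, e) all(s <= e), ann$starts, ann$ends)
  if (!all(ok)) {
    stop("start > end for event(s): ",
         paste(ann$event_id[!ok], collapse = ", "))
  }
  bad_incl <- !is.na(ann$inclusion_junction) &
    (ann$inclusion_junction < 1 | ann$inclusion_junction > n_s)
  if (any(bad_incl)) {
    stop("inclusion_junction out of range for event(s): ",
         paste(ann$event_id[bad_incl], collapse = ", "))
  }
  ann
}

#' Read event annotations from a BED-like TSV
#'
#' Columns: `event_id`, `gene_id`, `chrom`, `strand`, `as_type`,
#' `subjunction_starts`, `subjunction_ends` (comma-separated 1-based
#' inclusive coordinates) and optionally `inclusion_junction`.
#'
#' @param path Path to the TSV file.
#' @return Annotation tibble (see [event_annotations()]).
#' @export
read_event_annotations <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("event_id", "gene_id", "chrom", "strand", "as_type",
           "subjunction_starts", "subjunction_ends")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  }
  split_ints <- function(x) lapply(strsplit(x, ","), as.integer)
  event_annotations(
    event_id = tab$event_id, gene_id = tab$gene_id, chrom = tab$chrom,
    strand = tab$strand, as_type = tab$as_type,
    starts = split_ints(tab$subjunction_starts),
    ends = split_ints(tab$subjunction_ends),
    inclusion_junction = if ("inclusion_junction" %in% names(tab)) {
      as.integer(tab$inclusion_junction)
    } else {
      NA_integer_
    }
  )
}

#' @rdname read_event_annotations
#' @param annotations Annotation tibble.
#' @export
write_event_annotations <- function(annotations, path) {
  out <- tibble::tibble(
    event_id = annotations$event_id,
    gene_id = annotations$gene_id,
    chrom = annotations$chrom,
    strand = annotations$strand,
    as_type = annotations$as_type,
    subjunction_starts = vapply(annotations$starts, paste,
                                character(1), collapse = ","),
    subjunction_ends = vapply(annotations$ends, paste,
                              character(1), collapse = ","),
    inclusion_junction = annotations$inclusion_junction
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read per-replicate junction counts
#'
#' The TSV has columns `event_id`, `subjunction_index` and one column of
#' non-negative integer read counts per sample. Empty cells are treated as
#' zero with a warning; sample columns not present in the sample map are a
#' hard error.
#'
#' @param path Path to the counts TSV.
#' @param sample_map Sample-map tibble.
#' @return A `junction_counts` object: a long tibble of
#'   (`event_id`, `subjunction_index`, `sample_id`, `count`) with the sample
#'   map attached.
#' @export
read_junction_counts <- function(path, sample_map) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    event_id = "c", subjunction_index = "i", .default = "d"
  ), progress = FALSE)
  req <- c("event_id", "subjunction_index")
  if (!all(req %in% names(tab))) {
    stop("counts file must have columns event_id and subjunction_index")
  }
  samples <- setdiff(names(tab), req)
  unknown <- setdiff(samples, sample_map$sample_id)
  if (length(unknown) > 0) {
    stop("sample column(s) not in sample map: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(sample_map$sample_id, samples)
  if (length(absent) > 0) {
    warning("sample(s) in map with no counts column: ",
            paste(absent, collapse = ", "))
  }
  long <- tidyr::pivot_longer(tab, cols = dplyr::all_of(samples),
                              names_to = "sample_id", values_to = "count")
  if (anyNA(long$count)) {
    warning(sum(is.na(long$count)), " missing count cell(s) treated as 0")
    long$count[is.na(long$count)] <- 0
  }
  bad <- long$count < 0 | long$count != floor(long$count)
  if (any(bad)) {
    # report in file-row terms: data rows are 1-based after the header
    row_in_file <- match(long$event_id[bad][1], tab$event_id)
    stop("negative or non-integer count (first at data row ", row_in_file,
         ", sample ", long$sample_id[bad][1], ")")
  }
  long$count <- as.integer(long$count)
  junction_counts(long, sample_map)
}

#' @rdname read_junction_counts
#' @param counts Long tibble of (`event_id`, `subjunction_index`,
#'   `sample_id`, `count`).
#' @export
junction_counts <- function(counts, sample_map) {
  req <- c("event_id", "subjunction_index", "sample_id", "count")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  unknown <- setdiff(unique(counts$sample_id), sample_map$sample_id)
  if (length(unknown) > 0) {
    stop("count sample(s) not in sample map: ",
         paste(unknown, collapse = ", "))
  }
  if (any(counts$count < 0)) stop("negative counts")
  out <- tibble::as_tibble(counts[req])
  out <- dplyr::arrange(out, .data$event_id, .data$subjunction_index,
                        match(.data$sample_id, sample_map$sample_id))
  structure(list(counts = out, sample_map = sample_map),
            class = "junction_counts")
}

#' @rdname read_junction_counts
#' @export
write_junction_counts <- function(counts, path) {
  stopifnot(inherits(counts, "junction_counts"))
  wide <- tidyr::pivot_wider(counts$counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  wide <- dplyr::arrange(wide, .data$event_id, .data$subjunction_index)
  ord <- intersect(counts$sample_map$sample_id, names(wide))
  wide <- wide[c("event_id", "subjunction_index", ord)]
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @export
print.junction_counts <- function(x, ...) {
  cat("junction_counts:", length(unique(x$counts$event_id)), "events,",
      nrow(x$sample_map), "samples\n")
  invisible(x)
}

#' Read a precomputed PSI table
#'
#' TSV of `event_id` by sample with fractional PSI values in [0, 1]; empty
#' cells mean undetected (distinct from a PSI of 0) and are stored as `NA`.
#'
#' @param path Path to the TSV.
#' @param sample_map Optional sample map; required for downstream pairwise
#'   comparisons.
#' @param annotations Optional annotations; when provided, sub-junction usage
#'   for two-junction events is reconstructed so that first-junction deltas
#'   are available downstream.
#' @return A `psi_table` object.
#' @export
read_psi_table <- function(path, sample_map = NULL, annotations = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    event_id = "c", .default = "d"
  ), progress = FALSE)
  if (!"event_id" %in% names(tab)) stop("PSI table must have column event_id")
  samples <- setdiff(names(tab), "event_id")
  psi <- as.matrix(tab[samples])
  rownames(psi) <- tab$event_id
  bad <- psi < 0 | psi > 1
  if (any(bad, na.rm = TRUE)) {
    idx <- which(bad)[1]
    stop("PSI value outside [0,1]: ", psi[idx])
  }
  if (is.null(sample_map)) {
    sample_map <- suppressWarnings(sample_map(samples, samples))
  }
  new_psi_table(psi = psi, sample_map = sample_map,
                annotations = annotations)
}

#' Write a PSI table (events by samples, fractions, 6 decimals)
#'
#' @param psi A `psi_table`.
#' @param path Output TSV path.
#' @export
write_psi_table <- function(psi, path) {
  stopifnot(inherits(psi, "psi_table"))
  m <- psi$psi
  out <- tibble::as_tibble(
    apply(m, 2, function(x) ifelse(is.na(x), NA_character_,
                                   sprintf("%.6f", x))),
    .name_repair = "minimal"
  )
  out <- dplyr::bind_cols(tibble::tibble(event_id = rownames(m)), out)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write any results tibble as deterministic TSV
#'
#' Column order is preserved; `NA` becomes an empty field; output is
#' byte-identical for identical input.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @export
write_results_tsv <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path, na = "",
                   progress = FALSE)
  invisible(path)
}

#' Export one event's cell-type inclusion levels for spatial visualization
#'
#' Writes a per-cell-type table (`cell_type`, `percent_spliced_in` on a
#' 0-100 scale with one decimal, `n_replicates`) suitable for a spatial
#' heatmap front end. Cell types where the event was undetected are omitted.
#'
#' @param usage Usage matrix tibble from [usage_mega_matrix()].
#' @param event_id Event to export.
#' @param path Output TSV path.
#' @export
export_vista_table <- function(usage, event_id, path) {
  if (nrow(usage) == 0) stop("empty usage matrix")
  rows <- usage[usage$event_id == event_id, ]
  if (nrow(rows) == 0) {
    d <- utils::adist(event_id, unique(usage$event_id))
    near <- unique(usage$event_id)[order(d)][seq_len(min(3, length(unique(usage$event_id))))]
    stop("event '", event_id, "' not in usage matrix; nearest: ",
         paste(near, collapse = ", "))
  }
  rows <- rows[!is.na(rows$usage), ]
  out <- tibble::tibble(
    cell_type = rows$cell_type,
    percent_spliced_in = sprintf("%.1f", 100 * rows$usage),
    n_replicates = rows$n_replicates
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
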