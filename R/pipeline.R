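#' Pipeline run configuration
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving the simulation stage.
#' @param thresholds Thresholds from [as_config()].
#' @param sim Named list of overrides for [sim_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, thresholds = as_config(),
                       sim = list()) {
  stopifnot(inherits(thresholds, "spliceuniq_config"))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 thresholds = thresholds, sim = sim),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Top-level keys: `outdir`, `seed`, `thresholds` (flat map, see
#' [as_config()]) and `sim` (overrides for [sim_config()]).
#'
#' @param path YAML file path.
#' @param outdir Optional override of the configured output directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, outdir = NULL) {
  vals <- yaml::read_yaml(path)
  run_config(
    outdir = outdir %||% vals$outdir %||% ".",
    seed = vals$seed %||% 1,
    thresholds = do.call(as_config, vals$thresholds %||% list()),
    sim = vals$sim %||% list()
  )
}

out_path <- function(rc, name) file.path(rc$outdir, name)

req_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing input ", path, "; run `", produced_by, "` first")
  }
  path
}

# remove declared outputs if the writing code fails midway
writing <- function(paths, code) {
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))
  force(code)
  ok <- TRUE
  invisible(paths)
}

write_run_log <- function(rc) {
  log <- list(
    tool = "spliceuniq",
    version = as.character(utils::packageVersion("spliceuniq")),
    seed = rc$seed,
    thresholds = lapply(unclass(rc$thresholds), identity),
    sim_overrides = rc$sim
  )
  yaml::write_yaml(log, out_path(rc, "run_log.yaml"))
}

#' Pipeline stages
#'
#' Each `cmd_*` function reads its inputs from the run directory, writes its
#' module's TSV outputs plus a run log, and fails with a clean error (and no
#' partial outputs) when an upstream file is missing. [run_pipeline()]
#' chains simulate, PSI, pairwise comparison, uniqueness, global statistics,
#' mega matrices and the spatial export.
#'
#' @param rc A [run_config()].
#' @return The written file paths, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(rc) {
  dir.create(rc$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(sim_config, c(rc$sim, list(seed = rc$seed)))
  sim <- simulate_splicing(cfg)
  expr <- simulate_expression(cfg)
  paths <- out_path(rc, c("sample_map.tsv", "annotations.tsv",
                          "junction_counts.tsv", "truth.tsv",
                          "expr_counts.tsv", "expr_truth.tsv"))
  writing(paths, {
    write_sample_map(sim$sample_map, paths[1])
    write_event_annotations(sim$annotations, paths[2])
    write_junction_counts(sim$counts, paths[3])
    write_results_tsv(sim$truth, paths[4])
    write_results_tsv(
      dplyr::bind_cols(tibble::tibble(gene_id = rownames(expr$counts)),
                       tibble::as_tibble(expr$counts)), paths[5])
    write_results_tsv(expr$truth, paths[6])
  })
  write_run_log(rc)
  invisible(paths)
}

load_psi <- function(rc) {
  smap <- read_sample_map(req_file(out_path(rc, "sample_map.tsv"),
                                   "simulate"))
  ann <- read_event_annotations(req_file(out_path(rc, "annotations.tsv"),
                                         "simulate"))
  counts <- read_junction_counts(req_file(out_path(rc, "junction_counts.tsv"),
                                          "simulate"), smap)
  compute_psi(counts, filter_multi_coordinate(ann), rc$thresholds)
}

#' @rdname pipeline
#' @export
cmd_psi <- function(rc) {
  psi <- load_psi(rc)
  p <- out_path(rc, "psi.tsv")
  writing(p, write_psi_table(psi, p))
  write_run_log(rc)
  invisible(p)
}

#' @rdname pipeline
#' @export
cmd_compare <- function(rc) {
  psi <- load_psi(rc)
  comp <- run_all_pairs(psi, rc$thresholds)
  p <- out_path(rc, "comparisons.tsv")
  writing(p, write_results_tsv(comp, p))
  write_run_log(rc)
  invisible(p)
}

read_comparisons <- function(rc) {
  path <- req_file(out_path(rc, "comparisons.tsv"), "compare")
  readr::read_tsv(path, col_types = readr::cols(
    as_type = "c", event_id = "c", cell_a = "c", cell_b = "c",
    significant = "l", n_a = "i", n_b = "i", .default = "d"
  ), progress = FALSE)
}

#' @rdname pipeline
#' @export
cmd_uniqueness <- function(rc) {
  comp <- read_comparisons(rc)
  ann <- read_event_annotations(req_file(out_path(rc, "annotations.tsv"),
                                         "simulate"))
  uniq <- uniqueness_table(comp, ann)
  paths <- out_path(rc, "uniqueness.tsv")
  expr_path <- out_path(rc, "expr_counts.tsv")
  writing(paths, write_results_tsv(uniq, paths))
  if (file.exists(expr_path)) {
    tab <- readr::read_tsv(expr_path, col_types = readr::cols(
      gene_id = "c", .default = "d"), progress = FALSE)
    m <- as.matrix(tab[-1])
    rownames(m) <- tab$gene_id
    smap <- read_sample_map(req_file(out_path(rc, "sample_map.tsv"),
                                     "simulate"))
    eu <- expression_uniqueness_table(
      run_expression_pairs(m, smap, rc$thresholds))
    p2 <- out_path(rc, "expression_uniqueness.tsv")
    writing(p2, write_results_tsv(eu, p2))
    paths <- c(paths, p2)
  }
  write_run_log(rc)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_stats <- function(rc) {
  comp <- read_comparisons(rc)
  ann <- read_event_annotations(req_file(out_path(rc, "annotations.tsv"),
                                         "simulate"))
  counts <- count_differential(comp)
  totals <- global_totals(comp, ann, rc$thresholds)
  uniq <- uniqueness_table(comp, ann)
  cells <- sort(unique(c(comp$cell_a, comp$cell_b)))
  bias <- tidyr::crossing(cell_type = cells,
                          as_type = sort(unique(comp$as_type)))
  bias$fraction_upstream <- mapply(
    function(ct, t) directional_bias(uniq, ct, t),
    bias$cell_type, bias$as_type)
  corr <- splice_type_correlation(counts)
  corr_tab <- dplyr::bind_cols(tibble::tibble(category = rownames(corr)),
                               tibble::as_tibble(corr))
  outl <- dplyr::bind_rows(lapply(sort(unique(counts$as_type)), function(t) {
    dplyr::bind_cols(tibble::tibble(as_type = t), outlier_cells(counts, t))
  }))
  paths <- out_path(rc, c("counts_by_pair.tsv", "global_totals.tsv",
                          "correlations.tsv", "bias.tsv", "outliers.tsv"))
  writing(paths, {
    write_results_tsv(counts, paths[1])
    write_results_tsv(totals, paths[2])
    write_results_tsv(corr_tab, paths[3])
    write_results_tsv(bias, paths[4])
    write_results_tsv(outl, paths[5])
  })
  write_run_log(rc)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_megamatrix <- function(rc) {
  psi <- load_psi(rc)
  usage <- usage_mega_matrix(psi)
  p <- out_path(rc, "usage.tsv")
  writing(p, write_results_tsv(usage, p))
  paths <- write_mega_matrices(usage, rc$outdir)
  write_run_log(rc)
  invisible(c(p, paths))
}

#' @rdname pipeline
#' @param event_id Event to export; defaults to the top-ranked event of the
#'   uniqueness table.
#' @export
cmd_export <- function(rc, event_id = NULL) {
  upath <- req_file(out_path(rc, "usage.tsv"), "megamatrix")
  usage <- readr::read_tsv(upath, col_types = readr::cols(
    as_type = "c", event_id = "c", cell_type = "c", usage = "d",
    n_replicates = "i"), progress = FALSE)
  if (is.null(event_id)) {
    uniq <- readr::read_tsv(req_file(out_path(rc, "uniqueness.tsv"),
                                     "uniqueness"),
                            col_types = readr::cols(
                              as_type = "c", feature_id = "c",
                              focal_cell = "c", .default = "d"),
                            progress = FALSE)
    event_id <- uniq$feature_id[1]
  }
  p <- out_path(rc, paste0("vista_", event_id, ".tsv"))
  writing(p, export_vista_table(usage, event_id, p))
  write_run_log(rc)
  invisible(p)
}

#' @rdname pipeline
#' @export
run_pipeline <- function(rc) {
  paths <- c(
    cmd_simulate(rc), cmd_psi(rc), cmd_compare(rc), cmd_uniqueness(rc),
    cmd_stats(rc), cmd_megamatrix(rc), cmd_export(rc)
  )
  invisible(paths)
}
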