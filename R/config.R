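#' Analysis thresholds
#'
#' Builds the flat list of thresholds used throughout the pipeline. Defaults
#' mirror a conservative junction-level differential-splicing analysis:
#' events need at least `junction_min_reads` junction-spanning reads per
#' replicate to be quantified, a call requires both an effect size
#' (`delta_psi_min`, fractional PSI units) and significance (`p_max`,
#' `q_max`), differential expression uses the stricter `expr_p_max` /
#' `expr_lfc_min` gates, and an event only enters global tallies when called
#' differential in at least `global_min_comparisons` pairwise comparisons.
#'
#' @param junction_min_reads Minimum junction reads per event and replicate
#'   for the replicate to count as detected (default 5).
#' @param delta_psi_min Minimum |delta PSI| (fraction) for significance
#'   (default 0.10; the gate is strict, i.e. `> 0.10`).
#' @param p_max,q_max Maximum p-value and BH q-value for a significant
#'   splicing call (defaults 0.05).
#' @param expr_p_max Maximum p-value for differential expression (default 0.01).
#' @param expr_lfc_min Minimum |log2 fold change| for differential expression
#'   (default 2; strict).
#' @param global_min_comparisons Minimum number of significant pairwise
#'   comparisons for an event to enter global totals (default 5).
#' @param ... Ignored; guards against misspelled threshold names.
#' @return A named list of class `spliceuniq_config`.
#' @export
as_config <- function(junction_min_reads = 5,
                      delta_psi_min = 0.10,
                      p_max = 0.05,
                      q_max = 0.05,
                      expr_p_max = 0.01,
                      expr_lfc_min = 2,
                      global_min_comparisons = 5,
                      ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown config field(s): ", paste(names(extra), collapse = ", "))
  }
  cfg <- list(
    junction_min_reads = junction_min_reads,
    delta_psi_min = delta_psi_min,
    p_max = p_max,
    q_max = q_max,
    expr_p_max = expr_p_max,
    expr_lfc_min = expr_lfc_min,
    global_min_comparisons = global_min_comparisons
  )
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1 && x >= 0, logical(1))
  if (!all(num)) stop("all thresholds must be single non-negative numbers")
  structure(cfg, class = "spliceuniq_config")
}

#' Read thresholds from a YAML config file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [as_config()].
#'
#' @param path Path to a flat YAML file of threshold names and values.
#' @return A `spliceuniq_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(as_config, vals)
}

#' @export
print.spliceuniq_config <- function(x, ...) {
  cat("spliceuniq thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
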