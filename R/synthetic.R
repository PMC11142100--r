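#' Simulation configuration
#'
#' Defaults emulate the shape of a deep sorted-cell neuronal atlas: 46 cell
#' types with 4 biological replicates each, six splicing-event classes, a
#' mean of 200 junction-spanning reads per event and sample, beta-distributed
#' replicate PSI noise (concentration 100), and 5% of events planted as
#' cell-unique with a PSI shift of 0.6 in one focal cell type.
#'
#' @param n_cell_types Number of cell types (default 46).
#' @param n_replicates Replicates per cell type; scalar or per-cell vector
#'   (default 4).
#' @param events_per_type Named integer vector of event counts per splicing
#'   class.
#' @param depth Mean total junction reads per event and sample (Poisson,
#'   default 200).
#' @param concentration Beta concentration for replicate PSI noise
#'   (default 100).
#' @param planted_fraction Fraction of events made cell-unique (default 0.05).
#' @param effect Planted PSI shift, fractional units (default 0.6); planted
#'   means are clipped into [0.02, 0.98].
#' @param n_genes Genes for the expression simulation (default 200).
#' @param expr_mean Median of the lognormal gene baseline mean (default 100).
#' @param expr_dispersion Negative-binomial dispersion (default 0.1).
#' @param expr_fold Planted expression fold change (default 16).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cell_types = 46,
                       n_replicates = 4,
                       events_per_type = c(CASSETTE = 10, MXE = 10,
                                           A5S = 10, A3S = 10, IR = 10,
                                           COMPOSITE = 10),
                       depth = 200,
                       concentration = 100,
                       planted_fraction = 0.05,
                       effect = 0.6,
                       n_genes = 200,
                       expr_mean = 100,
                       expr_dispersion = 0.1,
                       expr_fold = 16,
                       seed = 1) {
  events_per_type <- unlist(events_per_type)
  check_as_type(names(events_per_type))
  cfg <- list(n_cell_types = n_cell_types, n_replicates = n_replicates,
              events_per_type = events_per_type, depth = depth,
              concentration = concentration,
              planted_fraction = planted_fraction, effect = effect,
              n_genes = n_genes, expr_mean = expr_mean,
              expr_dispersion = expr_dispersion, expr_fold = expr_fold,
              seed = as.integer(seed))
  pos <- c("n_cell_types", "n_replicates", "depth", "concentration",
           "n_genes", "expr_mean", "expr_dispersion", "expr_fold")
  for (nm in pos) {
    if (any(cfg[[nm]] <= 0)) stop(nm, " must be positive")
  }
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1) {
    stop("planted_fraction must be in [0,1]")
  }
  if (cfg$effect < 0 || cfg$effect > 1) stop("effect must be in [0,1]")
  structure(cfg, class = "sim_config")
}

sim_cell_types <- function(config) sprintf("CT%02d", seq_len(config$n_cell_types))

sim_sample_map <- function(config) {
  cells <- sim_cell_types(config)
  nrep <- rep_len(config$n_replicates, length(cells))
  sample_map(
    sample_id = unlist(mapply(function(ct, n) paste0(ct, "_r", seq_len(n)),
                              cells, nrep, SIMPLIFY = FALSE)),
    cell_type = rep(cells, nrep)
  )
}

sim_annotations <- function(config) {
  types <- rep(names(config$events_per_type), config$events_per_type)
  n <- length(types)
  if (n == 0) stop("no events configured")
  event_id <- sprintf("%s_%03d", types, stats::ave(seq_len(n), types,
                                                   FUN = seq_along))
  strand <- rep_len(c("+", "-"), n)
  chrom <- rep_len(paste0("chr", c("I", "II", "III", "IV", "V")), n)
  base <- 10000 + 2000 * seq_len(n)
  k <- ifelse(types == "COMPOSITE", 3L, 2L)
  starts <- lapply(seq_len(n), function(i) base[i] + 100L * (seq_len(k[i]) - 1L))
  ends <- lapply(seq_len(n), function(i) base[i] + 500L + 100L * (seq_len(k[i]) - 1L))
  incl <- ifelse(types %in% c("CASSETTE", "IR"),
                 rep_len(c(1L, 2L), n), NA_integer_)
  event_annotations(
    event_id = event_id, gene_id = sprintf("gene_%03d", seq_len(n)),
    chrom = chrom, strand = strand, as_type = types,
    starts = starts, ends = ends, inclusion_junction = incl
  )
}

#' Simulate junction counts with planted cell-unique events
#'
#' Per event a baseline mean PSI is drawn uniformly in [0.1, 0.9]; planted
#' events shift the focal cell's mean by the configured effect (away from
#' 0.5, clipped into [0.02, 0.98]). Replicate PSI follows a beta
#' distribution around the cell mean, total junction reads are Poisson, and
#' the representative junction's reads are binomial given the replicate PSI;
#' remaining reads are spread over the other sub-junctions with fixed
#' per-event proportions. Strands alternate so the orientation-reversal
#' paths for alternative splice sites are exercised on both strands.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a `junction_counts`), `annotations`,
#'   `sample_map` and `truth` (planted events with expected index sign).
#' @export
simulate_splicing <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    smap <- sim_sample_map(config)
    ann <- sim_annotations(config)
    cells <- sim_cell_types(config)
    n_ev <- nrow(ann)
    n_s <- nrow(smap)
    baseline <- stats::runif(n_ev, 0.1, 0.9)

    n_planted <- round(config$planted_fraction * n_ev)
    # baselines are uniform on [0.1, 0.9] and shifts point away from 0.5, so
    # the clipping probability is an analytic function of the effect size;
    # refuse configs where most planted events would hit the clip bounds
    clip_width <- max(0, 0.5 - max(0.1, 0.98 - config$effect))
    if (n_planted > 0 && 2 * clip_width / 0.8 > 0.5) {
      stop("infeasible config: planted effect would clip more than half of ",
           "the planted events")
    }
    planted <- if (n_planted > 0) sample(n_ev, n_planted) else integer(0)
    focal <- if (n_planted > 0) sample(cells, n_planted, replace = TRUE) else character(0)
    dir <- ifelse(baseline[planted] <= 0.5, 1, -1)
    raw_shift <- baseline[planted] + dir * config$effect
    shifted <- pmin(pmax(raw_shift, 0.02), 0.98)

    mu <- matrix(baseline, nrow = n_ev, ncol = length(cells),
                 dimnames = list(ann$event_id, cells))
    if (n_planted > 0) mu[cbind(planted, match(focal, cells))] <- shifted

    r_idx <- representative_indices(ann)
    f_idx <- first_junction_indices(ann)
    k <- lengths(ann$starts)
    # fixed per-event split of non-representative mass (composite events)
    w3 <- stats::runif(n_ev, 0.2, 0.8)

    mu_s <- mu[, smap$cell_type, drop = FALSE]
    kap <- config$concentration
    psi <- matrix(stats::rbeta(n_ev * n_s, mu_s * kap, (1 - mu_s) * kap),
                  n_ev, n_s)
    total <- matrix(stats::rpois(n_ev * n_s, config$depth), n_ev, n_s)
    rep_ct <- matrix(stats::rbinom(n_ev * n_s, total, psi), n_ev, n_s)
    rest <- total - rep_ct

    rows <- vector("list", n_ev)
    for (i in seq_len(n_ev)) {
      others <- setdiff(seq_len(k[i]), r_idx[i])
      cnt <- matrix(0L, nrow = k[i], ncol = n_s)
      cnt[r_idx[i], ] <- rep_ct[i, ]
      if (length(others) == 1) {
        cnt[others, ] <- rest[i, ]
      } else {
        first_other <- stats::rbinom(n_s, rest[i, ], w3[i])
        cnt[others[1], ] <- first_other
        cnt[others[2], ] <- rest[i, ] - first_other
      }
      rows[[i]] <- tibble::tibble(
        event_id = ann$event_id[i],
        subjunction_index = rep(seq_len(k[i]), times = n_s),
        sample_id = rep(smap$sample_id, each = k[i]),
        count = as.integer(cnt)
      )
    }
    long <- dplyr::bind_rows(rows)

    truth <- if (n_planted > 0) {
      osign <- orientation_sign(ann$as_type[planted], ann$strand[planted])
      first_sign <- ifelse(r_idx[planted] == f_idx[planted], 1, -1)
      planted_base <- baseline[planted]
      tibble::tibble(
        feature_id = ann$event_id[planted],
        focal_cell = focal,
        as_type = ann$as_type[planted],
        baseline = planted_base,
        shifted = shifted,
        true_effect = shifted - planted_base,
        direction = sign(shifted - planted_base) * first_sign * osign
      )
    } else {
      tibble::tibble(feature_id = character(), focal_cell = character(),
                     as_type = character(), baseline = numeric(),
                     shifted = numeric(), true_effect = numeric(),
                     direction = numeric())
    }
    list(counts = junction_counts(long, smap), annotations = ann,
         sample_map = smap, truth = truth)
  })
}

#' Simulate gene-level expression counts with planted cell-unique genes
#'
#' Counts follow a negative binomial per gene and sample; planted genes are
#' upregulated by the configured fold change in one focal cell type.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (gene-by-sample integer matrix),
#'   `sample_map` and `truth`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    smap <- sim_sample_map(config)
    cells <- sim_cell_types(config)
    g <- config$n_genes
    genes <- sprintf("g%04d", seq_len(g))
    base_mean <- stats::rlnorm(g, log(config$expr_mean), 1)
    n_planted <- round(config$planted_fraction * g)
    planted <- if (n_planted > 0) sample(g, n_planted) else integer(0)
    focal <- if (n_planted > 0) sample(cells, n_planted, replace = TRUE) else character(0)
    mu <- matrix(base_mean, nrow = g, ncol = length(cells),
                 dimnames = list(genes, cells))
    if (n_planted > 0) {
      mu[cbind(planted, match(focal, cells))] <-
        base_mean[planted] * config$expr_fold
    }
    mu_s <- mu[, smap$cell_type, drop = FALSE]
    counts <- matrix(
      stats::rnbinom(g * nrow(smap), mu = mu_s,
                     size = 1 / config$expr_dispersion),
      nrow = g, dimnames = list(genes, smap$sample_id)
    )
    truth <- tibble::tibble(
      feature_id = genes[planted], focal_cell = focal,
      fold = rep(config$expr_fold, n_planted),
      base_mean = base_mean[planted],
      direction = rep(1, n_planted)
    )
    list(counts = counts, sample_map = smap, truth = truth)
  })
}

#' Evaluate recovery of planted features from a ranked uniqueness table
#'
#' @param uniq Ranked uniqueness table (`feature_id`, `focal_cell`,
#'   `index`), most unique first.
#' @param truth Truth tibble from the simulator.
#' @param k Cutoff for precision at k (default: number of planted features).
#' @return List with `precision_at_k`, `n_records` and a `ranks` tibble
#'   (rank of each planted (feature, focal-cell) record, plus whether the
#'   recovered index sign matches the planted direction).
#' @export
truth_eval <- function(uniq, truth, k = nrow(truth)) {
  missing <- setdiff(truth$feature_id, uniq$feature_id)
  if (length(missing) > 0) {
    stop("planted feature(s) absent from uniqueness table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  key <- paste(uniq$feature_id, uniq$focal_cell)
  tkey <- paste(truth$feature_id, truth$focal_cell)
  rank <- match(tkey, key)
  dir <- if ("direction" %in% names(truth)) truth$direction else NA_real_
  ranks <- tibble::tibble(
    feature_id = truth$feature_id,
    focal_cell = truth$focal_cell,
    rank = rank,
    index = uniq$index[rank],
    sign_match = sign(uniq$index[rank]) == sign(dir)
  )
  list(
    precision_at_k = if (k > 0) mean(key[seq_len(k)] %in% tkey) else NA_real_,
    n_records = nrow(uniq),
    ranks = ranks
  )
}
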