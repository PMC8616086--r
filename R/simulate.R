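#' Configure a synthetic miRNA-target study
#'
#' Bundles every parameter of the synthetic-data generator: the gene universe,
#' the planted target set and its effect sizes, the negative-binomial noise
#' model, and the error rates of the simulated prediction algorithms. The same
#' configuration (including `seed`) always yields bit-identical tables.
#'
#' The generator emulates the design of a stable-cell overexpression screen
#' paired with RISC-trap pulldown sequencing: one control and one
#' miRNA-condition library per arm (replication is optional), planted
#' downregulation of targets in the stable cell, planted pulldown enrichment
#' of targets only in the cancer context, and five imperfect binary
#' target-prediction algorithms.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_targets Number of planted target genes (must not exceed `n_genes`).
#' @param library_size Expected total reads per library.
#' @param nb_dispersion Negative-binomial dispersion `phi` in the
#'   mean-dispersion parameterization `Var = mu + phi * mu^2`; `0` degenerates
#'   to Poisson sampling.
#' @param de_log2fc Planted log2 fold change of targets in the miRNA-expressing
#'   stable cell relative to control (typically negative).
#' @param pulldown_log2_enrich Planted log2 enrichment of targets in the
#'   cancer-context miRNA pulldown relative to the control-miRNA pulldown
#'   (typically positive).
#' @param predictor_sensitivity Probability that one prediction algorithm calls
#'   a true target.
#' @param predictor_specificity Probability that one prediction algorithm does
#'   not call a non-target.
#' @param n_predictors Number of simulated prediction algorithms.
#' @param n_replicates Libraries per condition in the stable-cell arm
#'   (defaults to 1, mirroring single-library study designs).
#' @param control_size_factor Multiplier on the control-pulldown library size,
#'   so the two pulldown totals differ and the totals term of the R_RC
#'   statistic is actually exercised.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal distribution of
#'   per-gene baseline expression before scaling to `library_size`.
#' @param seed Master integer seed; every table derives its own sub-stream
#'   from it, keyed by table name.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_experiment()], [simulate_stable_counts()],
#'   [simulate_pulldown_counts()], [simulate_predictions()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_targets = 10, seed = 1)
#' sim <- simulate_experiment(cfg)
#' names(sim)
sim_config <- function(n_genes = 2000,
                       n_targets = 50,
                       library_size = 1e6,
                       nb_dispersion = 0.05,
                       de_log2fc = -2,
                       pulldown_log2_enrich = 3,
                       predictor_sensitivity = 0.9,
                       predictor_specificity = 0.98,
                       n_predictors = 5,
                       n_replicates = 1,
                       control_size_factor = 0.7,
                       baseline_log2_mean = 6,
                       baseline_log2_sd = 2,
                       seed = 1) {
  if (!is_count_scalar(n_genes) || n_genes < 1) abort("`n_genes` must be a positive integer.")
  if (!is_count_scalar(n_targets)) abort("`n_targets` must be a non-negative integer.")
  if (n_targets > n_genes) abort("`n_targets` must not exceed `n_genes`.")
  if (!is.numeric(library_size) || library_size <= 0) abort("`library_size` must be positive.")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  if (!is_prob(predictor_sensitivity)) abort("`predictor_sensitivity` must be in [0, 1].")
  if (!is_prob(predictor_specificity)) abort("`predictor_specificity` must be in [0, 1].")
  if (!is_count_scalar(n_predictors) || n_predictors < 1) abort("`n_predictors` must be a positive integer.")
  if (!is_count_scalar(n_replicates) || n_replicates < 1) abort("`n_replicates` must be a positive integer.")
  if (!is.numeric(control_size_factor) || control_size_factor <= 0) {
    abort("`control_size_factor` must be positive.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) abort("`seed` must be an integer.")
  structure(
    list(
      n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
      library_size = library_size, nb_dispersion = nb_dispersion,
      de_log2fc = de_log2fc, pulldown_log2_enrich = pulldown_log2_enrich,
      predictor_sensitivity = predictor_sensitivity,
      predictor_specificity = predictor_specificity,
      n_predictors = as.integer(n_predictors),
      n_replicates = as.integer(n_replicates),
      control_size_factor = control_size_factor,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Gene universe, baseline expected counts, and planted target labels. Drawn
# from the "universe" sub-stream so every table of one configuration shares
# the same genes, baselines and targets.
sim_universe <- function(config) {
  with_stage_seed(config$seed, "universe", {
    gene <- sprintf("g%05d", seq_len(config$n_genes))
    rel <- 2^rnorm(config$n_genes, config$baseline_log2_mean, config$baseline_log2_sd)
    mu <- rel / sum(rel) * config$library_size
    targets <- sort(sample(gene, config$n_targets))
    list(gene = gene, mu = mu, targets = targets)
  })
}

sim_truth <- function(config, universe) {
  is_target <- universe$gene %in% universe$targets
  tibble(
    gene = universe$gene,
    is_target = is_target,
    de_log2fc = ifelse(is_target, config$de_log2fc, 0),
    pulldown_log2_enrich = ifelse(is_target, config$pulldown_log2_enrich, 0)
  )
}

# NB draw in the mean-dispersion form Var = mu + phi mu^2; phi = 0 is Poisson.
rnb <- function(n, mu, phi) {
  if (phi == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate stable-cell RNA-seq counts with planted downregulation
#'
#' Generates a gene-by-sample raw count table for a miRNA-overexpressing
#' stable cell line versus a vector control. Planted target genes have their
#' expected count multiplied by `2^de_log2fc` in the miRNA condition; counts
#' are negative-binomial with the configured dispersion (Poisson at
#' dispersion 0).
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble: `gene`, then `control_*` and `mir_*`
#'   sample columns of raw integer counts) and `truth` (tibble of planted
#'   labels and effects: `gene`, `is_target`, `de_log2fc`,
#'   `pulldown_log2_enrich`).
#' @export
#' @examples
#' sim <- simulate_stable_counts(sim_config(n_genes = 100, n_targets = 5))
#' dplyr::glimpse(sim$counts)
simulate_stable_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  uni <- sim_universe(config)
  mu_mir <- uni$mu * ifelse(uni$gene %in% uni$targets, 2^config$de_log2fc, 1)
  counts <- with_stage_seed(config$seed, "stable", {
    cols <- c(
      purrr::map(seq_len(config$n_replicates),
                 ~ rnb(config$n_genes, uni$mu, config$nb_dispersion)),
      purrr::map(seq_len(config$n_replicates),
                 ~ rnb(config$n_genes, mu_mir, config$nb_dispersion))
    )
    names(cols) <- c(paste0("control_", seq_len(config$n_replicates)),
                     paste0("mir_", seq_len(config$n_replicates)))
    tibble(gene = uni$gene, !!!cols)
  })
  list(counts = counts, truth = sim_truth(config, uni))
}

#' Simulate a RISC-trap pulldown pair
#'
#' Generates a two-column count table: the control-miRNA pulldown and the
#' miRNA-of-interest pulldown. In the `"cancer"` context, planted targets are
#' enriched `2^pulldown_log2_enrich`-fold in the miRNA pulldown; in the
#' `"normal"` context no gene is enriched, so the pair serves as the null
#' distribution for threshold calibration. The control-pulldown library size
#' is scaled by `control_size_factor`, so the two totals deliberately differ.
#'
#' @param config A [sim_config()].
#' @param context `"normal"` (no planted enrichment) or `"cancer"`.
#' @return A list with `counts` (tibble: `gene`, `control_pulldown`,
#'   `mir_pulldown`) and `truth` as in [simulate_stable_counts()].
#' @export
simulate_pulldown_counts <- function(config, context = c("normal", "cancer")) {
  stopifnot(inherits(config, "sim_config"))
  context <- match.arg(context)
  uni <- sim_universe(config)
  enrich <- if (context == "cancer") {
    ifelse(uni$gene %in% uni$targets, 2^config$pulldown_log2_enrich, 1)
  } else {
    rep(1, config$n_genes)
  }
  # totals are deliberately unconstrained: enrichment inflates the miR
  # pulldown and the control pulldown is scaled down, so the two library
  # sizes differ and the totals term of R_RC does real work
  mu_mir <- uni$mu * enrich
  mu_ctl <- uni$mu * config$control_size_factor
  counts <- with_stage_seed(config$seed, paste0("pulldown_", context), {
    tibble(
      gene = uni$gene,
      control_pulldown = rnb(config$n_genes, mu_ctl, config$nb_dispersion),
      mir_pulldown = rnb(config$n_genes, mu_mir, config$nb_dispersion)
    )
  })
  list(counts = counts, truth = sim_truth(config, uni))
}

#' Simulate target-prediction algorithm calls
#'
#' Each simulated algorithm calls each true target positive with probability
#' `predictor_sensitivity` and each non-target positive with probability
#' `1 - predictor_specificity`, independently across genes and algorithms.
#'
#' @param config A [sim_config()].
#' @param truth Planted-truth tibble from one of the `simulate_*` generators;
#'   defaults to the configuration's own truth.
#' @return A tibble with `gene` and one logical column per algorithm.
#' @export
simulate_predictions <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  uni <- sim_universe(config)
  if (is.null(truth)) truth <- sim_truth(config, uni)
  if (!all(truth$gene %in% uni$gene)) {
    abort("`truth` contains genes outside the configured universe.")
  }
  p_call <- ifelse(truth$is_target,
                   config$predictor_sensitivity,
                   1 - config$predictor_specificity)
  default_names <- c("miRanda", "miRDB", "miRWalk", "PicTar", "TargetScan")
  pred_names <- if (config$n_predictors <= length(default_names)) {
    default_names[seq_len(config$n_predictors)]
  } else {
    paste0("predictor_", seq_len(config$n_predictors))
  }
  with_stage_seed(config$seed, "predictions", {
    cols <- purrr::map(seq_len(config$n_predictors),
                       ~ rbinom(nrow(truth), 1, p_call) == 1)
    names(cols) <- pred_names
    tibble(gene = truth$gene, !!!cols)
  })
}

#' Simulate the full three-evidence study
#'
#' Convenience wrapper generating all four input tables of the triangulation
#' pipeline from one configuration: stable-cell counts, the normal- and
#' cancer-context pulldown pairs, and the prediction call table, plus the
#' shared planted truth.
#'
#' @param config A [sim_config()].
#' @return A named list: `stable`, `pulldown_normal`, `pulldown_cancer`
#'   (count tibbles), `predictions` (call tibble), `truth`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stable <- simulate_stable_counts(config)
  list(
    stable = stable$counts,
    pulldown_normal = simulate_pulldown_counts(config, "normal")$counts,
    pulldown_cancer = simulate_pulldown_counts(config, "cancer")$counts,
    predictions = simulate_predictions(config, stable$truth),
    truth = stable$truth
  )
}
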