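#' Pipeline configuration
#'
#' Collects every numeric threshold of the triangulation pipeline in one
#' validated object that is echoed verbatim into the provenance of each
#' report.
#'
#' @param min_count Low-count filter threshold on raw counts (default 2).
#' @param filter_scope `"all"` (every library must reach `min_count`) or
#'   `"any"`.
#' @param fc_threshold Fold-change selection threshold for the downregulation
#'   screen (default 0.5, i.e. more than 2-fold down; strict comparison).
#' @param de_pseudocount Pseudocount added to normalized condition means
#'   (default 1).
#' @param rrc_pseudocount Pseudocount `f` of the R_RC statistic (default 0.5).
#' @param rrc_quantile Calibration quantile for the enrichment threshold,
#'   in (0, 1) (default 0.95 — the top 5 percent of the control context).
#' @param min_votes Minimum predictor votes for the consensus (default 4).
#' @param trps_top_k Number of top TRPS technical replicates to average
#'   (default 3).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_count = 2,
                            filter_scope = c("all", "any"),
                            fc_threshold = 0.5,
                            de_pseudocount = 1,
                            rrc_pseudocount = 0.5,
                            rrc_quantile = 0.95,
                            min_votes = 4,
                            trps_top_k = 3) {
  filter_scope <- match.arg(filter_scope)
  if (!is_count_scalar(min_count)) abort("`min_count` must be a non-negative integer.")
  if (!is.numeric(fc_threshold) || fc_threshold <= 0) abort("`fc_threshold` must be positive.")
  if (!is.numeric(de_pseudocount) || de_pseudocount < 0) abort("`de_pseudocount` must be >= 0.")
  if (!is.numeric(rrc_pseudocount) || rrc_pseudocount <= 0) {
    abort("`rrc_pseudocount` (f) must be strictly positive.")
  }
  if (!is.numeric(rrc_quantile) || rrc_quantile <= 0 || rrc_quantile >= 1) {
    abort("`rrc_quantile` must be strictly between 0 and 1.")
  }
  if (!is_count_scalar(min_votes) || min_votes < 1) abort("`min_votes` must be a positive integer.")
  if (!is_count_scalar(trps_top_k) || trps_top_k < 1) abort("`trps_top_k` must be a positive integer.")
  structure(
    list(
      min_count = as.integer(min_count),
      filter_scope = filter_scope,
      fc_threshold = fc_threshold,
      de_pseudocount = de_pseudocount,
      rrc_pseudocount = rrc_pseudocount,
      rrc_quantile = rrc_quantile,
      min_votes = as.integer(min_votes),
      trps_top_k = as.integer(trps_top_k)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Parse and validate a key-value configuration document
#'
#' Reads `key = value` lines (blank lines and `#` comments ignored) into a
#' fully defaulted [pipeline_config()]. Unknown keys and out-of-domain values
#' are rejected with the offending key named. An empty document yields the
#' documented defaults.
#'
#' @param text Either a character vector of configuration lines or the path
#'   to a configuration file.
#' @return A validated `pipeline_config`.
#' @export
#' @examples
#' validate_config(c("fc_threshold = 0.4", "min_votes = 3"))
validate_config <- function(text = character()) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text) else text
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  opts <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("malformed configuration line: `%s` (expected key = value).", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    opts[[key]] <- val
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(opts), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s.", paste(unknown, collapse = ", ")))
  }
  numeric_keys <- setdiff(known, "filter_scope")
  args <- purrr::imap(opts, function(v, k) {
    if (k %in% numeric_keys) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) abort(sprintf("configuration key `%s` must be numeric, got `%s`.", k, v))
      num
    } else {
      v
    }
  })
  do.call(pipeline_config, args)
}

#' Planted-target recovery benchmark
#'
#' Runs the full synthetic study end to end over a series of seeds and scores
#' the final target set of each run against the planted truth. Precision is
#' reported as `NA` when a run selects no targets at all.
#'
#' @param sim A [sim_config()]; its `seed` field is replaced by each element
#'   of `seeds` in turn.
#' @param config A [pipeline_config()].
#' @param seeds Integer vector of seeds (default `1:10`).
#' @return A tibble with one row per seed: `seed`, `n_final`, `n_true`,
#'   `tp`, `precision`, `recall`.
#' @export
#' @examples
#' \donttest{
#' bench <- run_recovery_benchmark(sim_config(n_genes = 500, n_targets = 20),
#'                                 seeds = 1:3)
#' dplyr::summarise(bench, mean_recall = mean(recall),
#'                  mean_precision = mean(precision, na.rm = TRUE))
#' }
run_recovery_benchmark <- function(sim, config = pipeline_config(), seeds = 1:10) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "pipeline_config"))
  purrr::map_dfr(seeds, function(s) {
    cfg <- sim
    cfg$seed <- as.integer(s)
    data <- simulate_experiment(cfg)
    report <- suppressWarnings(run_pipeline(
      data$stable, data$pulldown_normal, data$pulldown_cancer,
      data$predictions, config = config
    ))
    truth_genes <- data$truth$gene[data$truth$is_target]
    tp <- length(intersect(report$final_targets, truth_genes))
    n_final <- length(report$final_targets)
    tibble(
      seed = as.integer(s),
      n_final = n_final,
      n_true = length(truth_genes),
      tp = tp,
      precision = if (n_final > 0) tp / n_final else NA_real_,
      recall = if (length(truth_genes) > 0) tp / length(truth_genes) else NA_real_
    )
  })
}
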