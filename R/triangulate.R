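#' Consensus vote over target-prediction algorithms
#'
#' A gene passes the prediction evidence stream when at least `min_votes` of
#' the algorithms call it a target — "at least 4 out of 5" at the defaults.
#' Genes absent from the call table are explicit negatives (0 votes) and can
#' never pass.
#'
#' @param calls Tibble with `gene` and one logical (or 0/1) column per
#'   prediction algorithm.
#' @param min_votes Minimum number of positive calls (default 4); must not
#'   exceed the number of predictors.
#' @return A tibble `gene`, `votes`, `consensus` (logical).
#' @export
#' @examples
#' calls <- tibble::tibble(gene = c("A", "B"),
#'                         p1 = c(TRUE, TRUE), p2 = c(TRUE, TRUE),
#'                         p3 = c(TRUE, TRUE), p4 = c(TRUE, FALSE),
#'                         p5 = c(FALSE, FALSE))
#' consensus_predictions(calls)  # A passes 4-of-5, B does not
consensus_predictions <- function(calls, min_votes = 4) {
  if (!is.data.frame(calls) || !"gene" %in% names(calls)) {
    abort("`calls` must be a data frame with a `gene` column.")
  }
  pred_cols <- setdiff(names(calls), "gene")
  if (length(pred_cols) == 0) abort("`calls` has no predictor columns.")
  if (!is_count_scalar(min_votes) || min_votes < 1) {
    abort("`min_votes` must be a positive integer.")
  }
  if (min_votes > length(pred_cols)) {
    abort(sprintf("`min_votes` (%d) exceeds the number of predictors (%d).",
                  min_votes, length(pred_cols)))
  }
  m <- as.matrix(calls[pred_cols])
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) abort("predictor calls must be logical or 0/1.")
    m <- m == 1
  }
  votes <- rowSums(m)
  tibble(gene = calls$gene, votes = as.integer(votes),
         consensus = votes >= min_votes)
}

#' Intersect the three evidence streams into a target report
#'
#' The final target set is defined as the genes common to all three analyses:
#' downregulated in the stable cell, enriched in the pulldown, and called by
#' the predictor consensus. The report also carries all pairwise overlap
#' counts for a Venn-style summary.
#'
#' @param de,rrc,pred Character vectors of gene ids passing each evidence
#'   stream (downregulation screen, R_RC enrichment, prediction consensus).
#' @param support Optional tibble of per-gene supporting values (columns
#'   `gene` and any of `log2fc`, `rrc`, `votes`) merged into [tidy()] output.
#' @param params Optional named list of thresholds/configuration echoed into
#'   the report's provenance.
#' @return An object of class `target_report`. Gene vectors are stored
#'   deduplicated and lexicographically sorted.
#' @export
#' @examples
#' rep <- intersect_evidence(de = c("A", "B", "C"),
#'                           rrc = c("B", "C", "D"),
#'                           pred = c("C", "D", "E"))
#' rep$final_targets  # "C"
intersect_evidence <- function(de, rrc, pred, support = NULL, params = list()) {
  de <- sort(unique(as.character(de)))
  rrc <- sort(unique(as.character(rrc)))
  pred <- sort(unique(as.character(pred)))
  final <- sort(intersect(intersect(de, rrc), pred))
  stopifnot(all(final %in% de), all(final %in% rrc), all(final %in% pred))
  structure(
    list(
      de_genes = de,
      rrc_genes = rrc,
      pred_genes = pred,
      final_targets = final,
      overlap = c(
        de_rrc = length(intersect(de, rrc)),
        de_pred = length(intersect(de, pred)),
        rrc_pred = length(intersect(rrc, pred)),
        de_rrc_pred = length(final)
      ),
      support = support,
      params = params,
      version = as.character(packageVersion("mirtrio"))
    ),
    class = "target_report"
  )
}

#' @export
print.target_report <- function(x, ...) {
  cat("<target_report>\n")
  cat(sprintf("  downregulated (DE):        %d genes\n", length(x$de_genes)))
  cat(sprintf("  pulldown-enriched (R_RC):  %d genes\n", length(x$rrc_genes)))
  cat(sprintf("  prediction consensus:      %d genes\n", length(x$pred_genes)))
  cat(sprintf("  pairwise overlaps:         DE*RRC=%d DE*PRED=%d RRC*PRED=%d\n",
              x$overlap[["de_rrc"]], x$overlap[["de_pred"]], x$overlap[["rrc_pred"]]))
  cat(sprintf("  final targets (triple):    %d genes\n", length(x$final_targets)))
  if (length(x$final_targets) > 0) {
    cat("  ", paste(head(x$final_targets, 10), collapse = ", "),
        if (length(x$final_targets) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @describeIn intersect_evidence Per-gene tibble over the union of all
#'   evidence sets: membership flags, supporting values where available, and
#'   an optional `flagged` column for annotated genes. Rows are ordered by
#'   descending R_RC, then ascending log2 fold change, then gene id.
#' @param x A `target_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.target_report <- function(x, ...) {
  all_genes <- sort(unique(c(x$de_genes, x$rrc_genes, x$pred_genes)))
  out <- tibble(
    gene = all_genes,
    in_de = all_genes %in% x$de_genes,
    in_rrc = all_genes %in% x$rrc_genes,
    in_pred = all_genes %in% x$pred_genes,
    final_target = all_genes %in% x$final_targets
  )
  if (!is.null(x$support)) {
    out <- dplyr::left_join(out, x$support, by = "gene")
  }
  if (!is.null(x$params$annotation_genes)) {
    out$flagged <- out$gene %in% x$params$annotation_genes
  }
  ord <- order(
    if ("rrc" %in% names(out)) -out$rrc else rep(0, nrow(out)),
    if ("log2fc" %in% names(out)) out$log2fc else rep(0, nrow(out)),
    out$gene
  )
  out[ord, , drop = FALSE]
}

#' @describeIn intersect_evidence One-row summary of evidence-set and overlap
#'   sizes.
#' @exportS3Method generics::glance
glance.target_report <- function(x, ...) {
  tibble(
    n_de = length(x$de_genes),
    n_rrc = length(x$rrc_genes),
    n_pred = length(x$pred_genes),
    n_de_rrc = unname(x$overlap[["de_rrc"]]),
    n_de_pred = unname(x$overlap[["de_pred"]]),
    n_rrc_pred = unname(x$overlap[["rrc_pred"]]),
    n_final = length(x$final_targets)
  )
}

#' @describeIn intersect_evidence Bar chart of evidence-set sizes, pairwise
#'   overlaps, and the final triple intersection.
#' @param object A `target_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.target_report <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    set = factor(
      c("DE", "R_RC", "Consensus", "DE∩R_RC", "DE∩Cons",
        "R_RC∩Cons", "Final"),
      levels = c("DE", "R_RC", "Consensus", "DE∩R_RC", "DE∩Cons",
                 "R_RC∩Cons", "Final")
    ),
    kind = c(rep("evidence set", 3), rep("pairwise overlap", 3), "triple intersection"),
    genes = c(g$n_de, g$n_rrc, g$n_pred, g$n_de_rrc, g$n_de_pred,
              g$n_rrc_pred, g$n_final)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$set, .data$genes, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genes), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Evidence sets and their intersections") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.title = ggplot2::element_blank())
}

#' Run the full three-evidence triangulation pipeline
#'
#' Executes the whole analysis: low-count filter, quantile normalization and
#' fold-change screen on the stable-cell table; low-count filter, R_RC and
#' threshold calibration on the normal-context pulldown; R_RC and enrichment
#' selection on the cancer-context pulldown; predictor consensus; and the
#' three-way intersection. Inputs may be tibbles or TSV paths. Any stage
#' failure is reported with the stage name.
#'
#' @param stable Stable-cell count table (tibble or TSV path) with control and
#'   miRNA-condition columns.
#' @param pulldown_normal,pulldown_cancer Pulldown pair count tables (tibble
#'   or TSV path).
#' @param predictions Prediction call table (tibble or TSV path).
#' @param config A [pipeline_config()] carrying every threshold.
#' @param control_samples,mir_samples Stable-cell condition columns; by
#'   default columns whose names start with `control` / `mir`.
#' @param pulldown_control_sample,pulldown_mir_sample Pulldown column names.
#' @param annotation_genes Optional character vector of genes of prior
#'   interest (e.g. vesicle-trafficking or disease-linked genes); these are
#'   flagged in [tidy()] output, never filtered on.
#' @param verbose Log one line per stage with gene counts in/out.
#' @return A `target_report` with per-gene support values and full parameter
#'   provenance in `$params`.
#' @export
run_pipeline <- function(stable, pulldown_normal, pulldown_cancer, predictions,
                         config = pipeline_config(),
                         control_samples = NULL, mir_samples = NULL,
                         pulldown_control_sample = "control_pulldown",
                         pulldown_mir_sample = "mir_pulldown",
                         annotation_genes = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  log_line <- function(...) if (verbose) message(sprintf(...))

  if (is.character(stable)) stable <- stage("read_stable", read_counts(stable))
  if (is.character(pulldown_normal)) {
    pulldown_normal <- stage("read_pulldown_normal", read_counts(pulldown_normal))
  }
  if (is.character(pulldown_cancer)) {
    pulldown_cancer <- stage("read_pulldown_cancer", read_counts(pulldown_cancer))
  }
  if (is.character(predictions)) {
    predictions <- stage("read_predictions", read_predictions(predictions))
  }

  smp <- sample_cols(stable)
  if (is.null(control_samples)) control_samples <- grep("^control", smp, value = TRUE)
  if (is.null(mir_samples)) mir_samples <- grep("^mir", smp, value = TRUE)

  # evidence stream 1: stable-cell downregulation
  de_screen <- stage("de_screen", {
    filtered <- filter_low_counts(stable, config$min_count, config$filter_scope)
    log_line("de_screen: low-count filter kept %d / %d genes",
             nrow(filtered), nrow(stable))
    normalized <- quantile_normalize(filtered)
    select_downregulated(normalized, control_samples, mir_samples,
                         fc_threshold = config$fc_threshold,
                         pseudocount = config$de_pseudocount)
  })
  de_genes <- de_screen$gene[de_screen$selected]
  log_line("de_screen: %d genes downregulated (fc < %g)",
           length(de_genes), config$fc_threshold)

  # evidence stream 2: pulldown enrichment, threshold calibrated on the
  # normal context where nothing should be enriched
  rrc_normal <- stage("rrc_normal", {
    filtered <- filter_low_counts(pulldown_normal, config$min_count, config$filter_scope)
    compute_rrc_table(filtered, pulldown_control_sample, pulldown_mir_sample,
                      pseudocount = config$rrc_pseudocount)
  })
  threshold <- stage("calibrate_threshold",
                     calibrate_threshold(rrc_normal, q = config$rrc_quantile))
  log_line("rrc: threshold %.4f (q = %g over %d normal-context genes)",
           threshold$threshold, config$rrc_quantile, threshold$n)
  rrc_cancer <- stage("rrc_cancer", {
    filtered <- filter_low_counts(pulldown_cancer, config$min_count, config$filter_scope)
    compute_rrc_table(filtered, pulldown_control_sample, pulldown_mir_sample,
                      pseudocount = config$rrc_pseudocount)
  })
  rrc_genes <- stage("select_enriched", select_enriched(rrc_cancer, threshold))
  log_line("rrc: %d / %d cancer-context genes enriched",
           length(rrc_genes), nrow(rrc_cancer))

  # evidence stream 3: prediction consensus
  consensus <- stage("consensus", consensus_predictions(predictions, config$min_votes))
  pred_genes <- consensus$gene[consensus$consensus]
  log_line("consensus: %d genes with >= %d votes", length(pred_genes), config$min_votes)

  support <- dplyr::full_join(
    dplyr::select(de_screen, "gene", "log2fc"),
    dplyr::select(rrc_cancer, "gene", "rrc"),
    by = "gene"
  )
  support <- dplyr::full_join(
    support, dplyr::select(consensus, "gene", "votes"), by = "gene"
  )

  report <- intersect_evidence(
    de = de_genes, rrc = rrc_genes, pred = pred_genes,
    support = support,
    params = list(
      min_count = config$min_count,
      filter_scope = config$filter_scope,
      fc_threshold = config$fc_threshold,
      de_pseudocount = config$de_pseudocount,
      rrc_pseudocount = config$rrc_pseudocount,
      rrc_quantile = config$rrc_quantile,
      rrc_threshold = threshold$threshold,
      min_votes = config$min_votes,
      control_samples = control_samples,
      mir_samples = mir_samples,
      annotation_genes = annotation_genes
    )
  )
  if (length(report$final_targets) == 0) {
    warn("final target set is empty.")
  }
  log_line("final: %d target genes", length(report$final_targets))
  report
}
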