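#' The R_RC pulldown enrichment statistic
#'
#' R_RC ("ratio of read count") is the log2 enrichment of a gene between two
#' RISC-trap pulldown libraries. Because the trapped mRNA pools differ in
#' complexity and total amount, ordinary between-sample normalization is not
#' justified; R_RC instead combines the per-gene ratio with a complementary
#' totals term that corrects for unequal captured-library sizes:
#'
#' \deqn{R_{RC} = \log_2\frac{n_2+f}{n_1+f} + \log_2\frac{t_1-n_1+f}{t_2-n_2+f}}
#'
#' where `n1`, `n2` are the gene's read counts in the control-miRNA pulldown
#' (sample 1) and the miRNA-of-interest pulldown (sample 2), `t1`, `t2` are
#' the total read counts of the two libraries, and `f > 0` is a pseudocount
#' keeping the ratios finite at zero counts. Positive values mean enrichment
#' by the miRNA of interest. The statistic is antisymmetric: swapping the two
#' samples negates it.
#'
#' @param n1,n2 Per-gene read counts in samples 1 (control pulldown) and 2
#'   (miRNA pulldown). Vectorized.
#' @param t1,t2 Total read counts over all genes in samples 1 and 2.
#' @param f Pseudocount, strictly positive (default 0.5, the conventional
#'   half count for log-ratio statistics).
#' @return Numeric vector of R_RC values (log2 units).
#' @export
#' @examples
#' compute_rrc(n1 = 10, n2 = 40, t1 = 10000, t2 = 10000, f = 0.5)
compute_rrc <- function(n1, n2, t1, t2, f = 0.5) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0) {
    abort("pseudocount `f` must be a single positive number.")
  }
  if (any(n1 < 0) || any(n2 < 0)) abort("counts must be non-negative.")
  if (any(n1 > t1) || any(n2 > t2)) {
    abort("per-gene counts cannot exceed their library totals (n1 <= t1, n2 <= t2).")
  }
  log2((n2 + f) / (n1 + f)) + log2((t1 - n1 + f) / (t2 - n2 + f))
}

#' Per-gene R_RC table for one pulldown pair
#'
#' Applies [compute_rrc()] to every gene of a two-sample pulldown count table,
#' with totals computed as the column sums of the (already low-count-filtered)
#' table itself.
#'
#' @param counts Count tibble with a `gene` column and the two pulldown
#'   sample columns.
#' @param control_sample,mir_sample Names of the control-miRNA and
#'   miRNA-of-interest pulldown columns. Default to the names emitted by
#'   [simulate_pulldown_counts()].
#' @param pseudocount Pseudocount `f` (default 0.5).
#' @return A tibble `gene`, `n1`, `n2`, `rrc`, carrying the totals and
#'   pseudocount used as attributes `t1`, `t2`, `pseudocount`.
#' @export
compute_rrc_table <- function(counts,
                              control_sample = "control_pulldown",
                              mir_sample = "mir_pulldown",
                              pseudocount = 0.5) {
  assert_counts(counts)
  smp <- sample_cols(counts)
  missing <- setdiff(c(control_sample, mir_sample), smp)
  if (length(missing) > 0) {
    abort(sprintf("sample column(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  n1 <- counts[[control_sample]]
  n2 <- counts[[mir_sample]]
  t1 <- sum(n1)
  t2 <- sum(n2)
  out <- tibble(
    gene = counts$gene,
    n1 = n1,
    n2 = n2,
    rrc = compute_rrc(n1, n2, t1, t2, pseudocount)
  )
  attr(out, "t1") <- t1
  attr(out, "t2") <- t2
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Calibrate the R_RC selection threshold from a control context
#'
#' The enrichment cutoff is data-derived, not a constant: it is the empirical
#' `q`-quantile (linear interpolation between order statistics, position
#' `1 + q * (n - 1)`) of the R_RC values computed in a context where no gene
#' is expected to be enriched — the "top 5 percent of the control" rule at the
#' default `q = 0.95`.
#'
#' @param control An R_RC table from [compute_rrc_table()] (or a bare numeric
#'   vector of R_RC values).
#' @param q Calibration quantile in (0, 1), default 0.95.
#' @return An object of class `rrc_threshold`: list with `threshold`,
#'   `quantile`, `n`.
#' @export
#' @examples
#' calibrate_threshold(seq(0.01, 1, by = 0.01), q = 0.95)  # threshold 0.9505
calibrate_threshold <- function(control, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    abort("`q` must be a single number strictly between 0 and 1.")
  }
  values <- if (is.data.frame(control)) control$rrc else control
  if (is.null(values) || length(values) == 0) {
    abort("control R_RC table is empty; cannot calibrate a threshold.")
  }
  structure(
    list(
      threshold = unname(quantile(values, q, type = 7)),
      quantile = q,
      n = length(values)
    ),
    class = "rrc_threshold"
  )
}

#' @export
print.rrc_threshold <- function(x, ...) {
  cat(sprintf("<rrc_threshold> %.4f (%.0f%% quantile of %d control R_RC values)\n",
              x$threshold, 100 * x$quantile, x$n))
  invisible(x)
}

#' Select genes enriched in the miRNA pulldown
#'
#' Returns the genes whose R_RC in the test (e.g. cancer-context) table is
#' strictly greater than the calibrated threshold.
#'
#' @param rrc An R_RC table from [compute_rrc_table()].
#' @param threshold An [calibrate_threshold()] object or a bare number.
#' @return Character vector of selected gene ids (input order preserved).
#' @export
select_enriched <- function(rrc, threshold) {
  thr <- if (inherits(threshold, "rrc_threshold")) threshold$threshold else threshold
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr)) {
    abort("`threshold` must be a number or an `rrc_threshold` object.")
  }
  rrc$gene[rrc$rrc > thr]
}
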