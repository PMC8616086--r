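#' Read a gene-by-sample count table from TSV
#'
#' Expects a header row, gene identifiers in the first column, and raw integer
#' counts in the remaining columns. Duplicate gene ids, negative counts,
#' non-integer counts and ragged rows are rejected with the offending line
#' identified (line numbers count the header as line 1).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble whose first column is `gene` followed by one numeric
#'   column per sample.
#' @export
read_counts <- function(path) {
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed count table `%s`: row width mismatch at line %d.",
                  path, probs$row[1] + 1L))
  }
  if (ncol(raw) < 2) abort(sprintf("`%s` has no sample columns.", path))
  names(raw)[1] <- "gene"
  if (anyDuplicated(raw$gene)) {
    dup <- raw$gene[duplicated(raw$gene)][1]
    abort(sprintf("duplicated gene id `%s` in `%s` (line %d).",
                  dup, path, which(raw$gene == dup)[2] + 1L))
  }
  for (s in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v) | v < 0 | v != trunc(v))
    if (length(bad) > 0) {
      abort(sprintf("invalid count `%s` in column `%s` of `%s` (line %d): counts must be non-negative integers.",
                    raw[[s]][bad[1]], s, path, bad[1] + 1L))
    }
    raw[[s]] <- v
  }
  assert_counts(raw)
}

#' Write a count (or any tabular) result as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a gene-by-predictor boolean call table from TSV
#'
#' Accepts `TRUE`/`FALSE` or `0`/`1` cells; any other value is an error.
#'
#' @param path Path to a tab-separated file with gene ids in the first column.
#' @return A tibble with `gene` and one logical column per predictor.
#' @export
read_predictions <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("`%s` has no predictor columns.", path))
  names(raw)[1] <- "gene"
  if (anyDuplicated(raw$gene)) {
    abort(sprintf("duplicated gene id in `%s`.", path))
  }
  for (s in names(raw)[-1]) {
    v <- toupper(trimws(raw[[s]]))
    ok <- v %in% c("TRUE", "FALSE", "0", "1")
    if (!all(ok)) {
      abort(sprintf("invalid call `%s` in column `%s` of `%s`: expected TRUE/FALSE or 0/1.",
                    raw[[s]][which(!ok)[1]], s, path))
    }
    raw[[s]] <- v %in% c("TRUE", "1")
  }
  raw
}

#' Drop genes with insufficient raw counts
#'
#' Implements the low-count pre-filter applied to raw (unnormalized) count
#' tables: a gene is retained only if its raw count reaches `min_count` in
#' every library (`scope = "all"`, the default) or in at least one library
#' (`scope = "any"`). Gene order is preserved and an empty result is allowed.
#'
#' @param counts Count tibble (`gene` column plus sample columns).
#' @param min_count Minimum raw count (default 2).
#' @param scope `"all"` (every library must reach `min_count`) or `"any"`.
#' @return The filtered count tibble.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("g1", "g2", "g3"),
#'                     a = c(2, 5, 0), b = c(2, 1, 0))
#' filter_low_counts(m)  # retains only g1
filter_low_counts <- function(counts, min_count = 2, scope = c("all", "any")) {
  assert_counts(counts)
  scope <- match.arg(scope)
  m <- as.matrix(counts[sample_cols(counts)])
  keep <- if (scope == "all") {
    rowSums(m >= min_count) == ncol(m)
  } else {
    rowSums(m >= min_count) >= 1
  }
  counts[keep, , drop = FALSE]
}

#' Quantile-normalize a count table
#'
#' Forces every sample's empirical distribution onto the common reference
#' distribution (the across-sample mean of order statistics), removing
#' systematic between-library differences while preserving within-sample rank
#' order. Tied values within a column receive the mean of the reference values
#' spanned by their ranks (averaged-ties convention). The operation is
#' idempotent.
#'
#' @param counts Count tibble (typically after [filter_low_counts()]).
#' @return A tibble of the same shape with normalized (generally non-integer)
#'   values.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("g1", "g2"), A = c(2, 6), B = c(4, 8))
#' quantile_normalize(m)  # both columns become (3, 7)
quantile_normalize <- function(counts) {
  assert_counts(counts)
  smp <- sample_cols(counts)
  m <- as.matrix(counts[smp])
  if (nrow(m) > 0) {
    norm <- limma::normalizeQuantiles(m, ties = TRUE)
    for (i in seq_along(smp)) counts[[smp[i]]] <- norm[, i]
  }
  counts
}

#' Screen for downregulated genes by fold change
#'
#' The stable-cell evidence stream: per gene, the fold change is
#' `(mean_mir + pseudocount) / (mean_control + pseudocount)` over normalized
#' expression, and a gene is selected when the fold change is strictly below
#' `fc_threshold` — "more than 2-fold down" at the default 0.5. With one
#' library per condition the condition mean is that single column.
#'
#' @param counts Normalized count tibble.
#' @param control_samples,mir_samples Character vectors of sample column names
#'   for the two conditions.
#' @param fc_threshold Selection threshold on the fold change (default 0.5);
#'   the comparison is strict.
#' @param pseudocount Added to both condition means to keep ratios finite
#'   (default 1).
#' @return A tibble: `gene`, `mean_control`, `mean_mir`, `fc`, `log2fc`,
#'   `selected`.
#' @export
select_downregulated <- function(counts, control_samples, mir_samples,
                                 fc_threshold = 0.5, pseudocount = 1) {
  assert_counts(counts)
  smp <- sample_cols(counts)
  unknown <- setdiff(c(control_samples, mir_samples), smp)
  if (length(unknown) > 0) {
    abort(sprintf("unknown sample id(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (length(control_samples) == 0 || length(mir_samples) == 0) {
    abort("both condition groups must contain at least one sample.")
  }
  if (!is.numeric(fc_threshold) || fc_threshold <= 0) abort("`fc_threshold` must be positive.")
  if (!is.numeric(pseudocount) || pseudocount < 0) abort("`pseudocount` must be >= 0.")
  mean_control <- rowMeans(counts[control_samples])
  mean_mir <- rowMeans(counts[mir_samples])
  fc <- (mean_mir + pseudocount) / (mean_control + pseudocount)
  tibble(
    gene = counts$gene,
    mean_control = mean_control,
    mean_mir = mean_mir,
    fc = fc,
    log2fc = log2(fc),
    selected = fc < fc_threshold
  )
}
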