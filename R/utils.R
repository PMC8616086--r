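# Internal helpers shared across modules.

# Deterministic sub-seed for a named stage, derived from the master seed by a
# stable polynomial string hash. Adding a stage never perturbs the stream of
# any other stage, because each stage re-seeds from its own name.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((seed %% 2147483647) * 7919 + h) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

# Sample (non-gene) columns of a counts tibble.
sample_cols <- function(counts) setdiff(names(counts), "gene")

assert_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || !"gene" %in% names(counts)) {
    abort(sprintf("`%s` must be a data frame with a `gene` column.", arg))
  }
  if (anyDuplicated(counts$gene)) {
    abort(sprintf("`%s` has duplicated gene ids: %s.", arg,
                  paste(unique(counts$gene[duplicated(counts$gene)]), collapse = ", ")))
  }
  smp <- sample_cols(counts)
  if (length(smp) == 0L) abort(sprintf("`%s` has no sample columns.", arg))
  for (s in smp) {
    if (!is.numeric(counts[[s]])) {
      abort(sprintf("column `%s` of `%s` is not numeric.", s, arg))
    }
    if (any(counts[[s]] < 0, na.rm = TRUE)) {
      abort(sprintf("column `%s` of `%s` contains negative counts.", s, arg))
    }
  }
  invisible(counts)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
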