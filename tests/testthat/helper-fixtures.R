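# Small fixtures shared across test files; everything is built in code.

toy_counts <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3"),
    a = c(2, 5, 0),
    b = c(2, 1, 0)
  )
}

# Random valid (n1, n2, t1, t2) tuples for R_RC property tests.
random_rrc_tuples <- function(n, seed = 42) {
  withr::with_seed(seed, {
    t1 <- sample(1000:100000, n, replace = TRUE)
    t2 <- sample(1000:100000, n, replace = TRUE)
    tibble::tibble(
      n1 = floor(runif(n) * t1),
      n2 = floor(runif(n) * t2),
      t1 = t1,
      t2 = t2
    )
  })
}

# Independent evaluation of the printed two-term R_RC formula, kept separate
# from the package implementation on purpose.
rrc_oracle <- function(n1, n2, t1, t2, f) {
  log2((n2 + f) / (n1 + f)) + log2((t1 - n1 + f) / (t2 - n2 + f))
}
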