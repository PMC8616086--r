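test_that("read_counts parses a well-formed table and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- tibble::tibble(gene = c("g1", "g2"), s1 = c(3, 0), s2 = c(7, 12))
  write_counts(m, path)
  expect_equal(read_counts(path), m)
})

test_that("read_counts rejects malformed input naming the offence", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t3", "g1\t4"), dup)
  expect_error(read_counts(dup), "duplicated gene id `g1`")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t-3"), neg)
  expect_error(read_counts(neg), "non-negative integers")

  frac <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t2.5"), frac)
  expect_error(read_counts(frac), "non-negative integers")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3"), ragged)
  expect_error(read_counts(ragged), "row width")
})

test_that("low-count filter keeps exactly the genes reaching min_count everywhere", {
  m <- toy_counts()  # g1=(2,2), g2=(5,1), g3=(0,0)
  expect_identical(filter_low_counts(m)$gene, "g1")
  # any-library variant keeps g2 as well
  expect_identical(filter_low_counts(m, scope = "any")$gene, c("g1", "g2"))
  # identity when everything passes; idempotence
  ok <- tibble::tibble(gene = c("a", "b"), s1 = c(2, 9), s2 = c(3, 2))
  expect_identical(filter_low_counts(ok), ok)
  expect_identical(filter_low_counts(filter_low_counts(m)), filter_low_counts(m))
  # empty result allowed
  expect_equal(nrow(filter_low_counts(m, min_count = 10)), 0)
})

test_that("quantile normalization reproduces hand-worked 2x2 examples", {
  m1 <- tibble::tibble(gene = c("g1", "g2"), A = c(2, 6), B = c(4, 8))
  n1 <- quantile_normalize(m1)
  expect_equal(n1$A, c(3, 7))
  expect_equal(n1$B, c(3, 7))

  m2 <- tibble::tibble(gene = c("g1", "g2"), A = c(10, 1), B = c(2, 20))
  n2 <- quantile_normalize(m2)
  expect_equal(n2$A, c(15, 1.5))
  expect_equal(n2$B, c(1.5, 15))  # rank reversal preserved

  # already-identical columns are unchanged
  m3 <- tibble::tibble(gene = c("g1", "g2", "g3"), A = c(5, 1, 9), B = c(5, 1, 9))
  expect_equal(quantile_normalize(m3), m3)
})

test_that("quantile normalization is idempotent, equalizes distributions, preserves ranks", {
  # tie-free matrices: both invariants hold exactly
  withr::with_seed(101, {
    for (i in 1:25) {
      m <- tibble::tibble(
        gene = sprintf("g%03d", 1:40),
        s1 = rlnorm(40, 4), s2 = rlnorm(40, 6), s3 = rlnorm(40, 2)
      )
      n <- quantile_normalize(m)
      # identical column order statistics
      expect_equal(sort(n$s1), sort(n$s2))
      expect_equal(sort(n$s1), sort(n$s3))
      # idempotence
      expect_equal(quantile_normalize(n), n)
      # within-column rank order preserved (up to ties)
      for (s in c("s1", "s2", "s3")) {
        expect_equal(rank(n[[s]], ties.method = "average"),
                     rank(m[[s]], ties.method = "average"))
      }
    }
  })
  # tied counts keep their ranks and remain approximately idempotent
  withr::with_seed(102, {
    m <- tibble::tibble(gene = sprintf("g%03d", 1:60),
                        s1 = rpois(60, 5), s2 = rpois(60, 50))
    n <- quantile_normalize(m)
    for (s in c("s1", "s2")) {
      expect_equal(rank(n[[s]], ties.method = "average"),
                   rank(m[[s]], ties.method = "average"))
    }
    expect_equal(quantile_normalize(n), n, tolerance = 0.02)
  })
})

test_that("tied values receive the mean of the reference values they span", {
  # reference = (3, 3.5, 6); the tie in A spans ranks 1-2 -> mean(3, 3.5)
  m <- tibble::tibble(gene = c("g1", "g2", "g3"), A = c(5, 5, 9), B = c(1, 2, 3))
  n <- quantile_normalize(m)
  expect_equal(n$A, c(3.25, 3.25, 6))
  expect_equal(n$B, c(3, 3.5, 6))
})

test_that("downregulation screen applies the strict pseudocounted fold-change rule", {
  m <- tibble::tibble(
    gene = c("down", "flat", "boundary"),
    control_1 = c(100, 50, 99),
    mir_1 = c(40, 50, 49)
  )
  res <- select_downregulated(m, "control_1", "mir_1")
  expect_equal(res$fc[1], 41 / 101)  # pseudocount of 1 on both means
  expect_true(res$selected[1])
  expect_equal(res$fc[2], 1)
  expect_false(res$selected[2])
  expect_equal(res$fc[3], 0.5)
  expect_false(res$selected[3])  # FC exactly at threshold is excluded

  expect_error(select_downregulated(m, "control_1", "nope"), "unknown sample")
  expect_error(select_downregulated(m, character(), "mir_1"), "at least one sample")
})

test_that("condition means average replicate columns", {
  m <- tibble::tibble(gene = "g", control_1 = 10, control_2 = 30, mir_1 = 4, mir_2 = 6)
  res <- select_downregulated(m, c("control_1", "control_2"), c("mir_1", "mir_2"))
  expect_equal(res$mean_control, 20)
  expect_equal(res$mean_mir, 5)
  expect_equal(res$fc, 6 / 21)
})
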