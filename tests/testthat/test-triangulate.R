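test_that("consensus vote counts positive calls per gene", {
  calls <- tibble::tibble(
    gene = c("four", "three", "five"),
    p1 = c(TRUE, TRUE, TRUE), p2 = c(TRUE, TRUE, TRUE),
    p3 = c(TRUE, TRUE, TRUE), p4 = c(TRUE, FALSE, TRUE),
    p5 = c(FALSE, FALSE, TRUE)
  )
  res <- consensus_predictions(calls, min_votes = 4)
  expect_equal(res$votes, c(4L, 3L, 5L))
  expect_equal(res$consensus, c(TRUE, FALSE, TRUE))
  # vote count equals the direct row sum of the boolean matrix
  expect_equal(res$votes, as.integer(rowSums(as.matrix(calls[-1]))))
  # 0/1 coding accepted
  calls01 <- dplyr::mutate(calls, dplyr::across(-gene, as.integer))
  expect_equal(consensus_predictions(calls01, 4), res)
  expect_error(consensus_predictions(calls, min_votes = 6), "exceeds")
})

test_that("evidence intersection is exact set arithmetic with pairwise counts", {
  rep <- intersect_evidence(de = c("A", "B", "C"), rrc = c("B", "C", "D"),
                            pred = c("C", "D", "E"))
  expect_identical(rep$final_targets, "C")
  expect_equal(unname(rep$overlap),
               c(2L, 1L, 2L, 1L)[c(1, 2, 3, 4)])
  expect_equal(rep$overlap[["de_rrc"]], 2L)
  expect_equal(rep$overlap[["de_pred"]], 1L)
  expect_equal(rep$overlap[["rrc_pred"]], 2L)

  same <- intersect_evidence(c("x", "y"), c("y", "x"), c("x", "y"))
  expect_identical(same$final_targets, c("x", "y"))
  empty <- intersect_evidence(character(0), c("a"), c("a"))
  expect_identical(empty$final_targets, character(0))

  # final set is contained in every evidence set
  expect_true(all(rep$final_targets %in% rep$de_genes))
  expect_true(all(rep$final_targets %in% rep$rrc_genes))
  expect_true(all(rep$final_targets %in% rep$pred_genes))
})

test_that("tidy and glance summarize a report consistently", {
  rep <- intersect_evidence(
    de = c("A", "B", "C"), rrc = c("B", "C", "D"), pred = c("C", "D", "E"),
    support = tibble::tibble(gene = LETTERS[1:5],
                             log2fc = c(-2, -1.5, -3, 0, 0.2),
                             rrc = c(0.5, 2, 3, 2.5, 0),
                             votes = c(1L, 2L, 5L, 4L, 4L))
  )
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
  expect_equal(td$gene[1], "C")  # highest R_RC first
  expect_identical(td$gene[td$final_target], "C")
  gl <- glance(rep)
  expect_equal(gl$n_final, 1)
  expect_equal(gl$n_de, 3)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("pipeline recovers planted targets and reports provenance", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_experiment(cfg)
  rep <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                       sim$pulldown_cancer, sim$predictions))
  truth <- sim$truth$gene[sim$truth$is_target]
  tp <- length(intersect(rep$final_targets, truth))
  expect_gte(tp / length(rep$final_targets), 0.9)
  expect_gte(tp / length(truth), 0.5)
  expect_equal(rep$params$rrc_quantile, 0.95)
  expect_true(is.numeric(rep$params$rrc_threshold))
  expect_true(all(rep$final_targets %in% rep$de_genes))
})

test_that("pipeline is deterministic and reads inputs from TSV identically", {
  cfg <- sim_config(n_genes = 400, n_targets = 20, seed = 3)
  sim <- simulate_experiment(cfg)
  r1 <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                      sim$pulldown_cancer, sim$predictions))
  r2 <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                      sim$pulldown_cancer, sim$predictions))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  dir <- withr::local_tempdir()
  paths <- list(stable = file.path(dir, "stable.tsv"),
                nrm = file.path(dir, "normal.tsv"),
                cnc = file.path(dir, "cancer.tsv"),
                prd = file.path(dir, "pred.tsv"))
  write_counts(sim$stable, paths$stable)
  write_counts(sim$pulldown_normal, paths$nrm)
  write_counts(sim$pulldown_cancer, paths$cnc)
  write_counts(sim$predictions, paths$prd)
  r3 <- suppressWarnings(run_pipeline(paths$stable, paths$nrm, paths$cnc, paths$prd))
  expect_identical(r1$final_targets, r3$final_targets)
  expect_identical(tidy(r1)$gene, tidy(r3)$gene)
})

test_that("null study yields an empty or near-empty final target set", {
  for (s in 1:3) {
    cfg <- sim_config(de_log2fc = 0, pulldown_log2_enrich = 0,
                      predictor_sensitivity = 0.02, predictor_specificity = 0.98,
                      seed = s)
    sim <- simulate_experiment(cfg)
    rep <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                         sim$pulldown_cancer, sim$predictions))
    expect_lte(length(rep$final_targets), 2)
  }
})

test_that("relaxing any threshold never shrinks the final target set", {
  cfg <- sim_config(n_genes = 800, n_targets = 40, seed = 4)
  sim <- simulate_experiment(cfg)
  base <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                        sim$pulldown_cancer, sim$predictions))
  relaxed <- list(
    pipeline_config(fc_threshold = 0.7),
    pipeline_config(rrc_quantile = 0.8),
    pipeline_config(min_votes = 3)
  )
  for (pc in relaxed) {
    rep <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                         sim$pulldown_cancer, sim$predictions,
                                         config = pc))
    expect_true(all(base$final_targets %in% rep$final_targets))
  }
})

test_that("annotation genes are flagged, not filtered", {
  cfg <- sim_config(n_genes = 400, n_targets = 20, seed = 5)
  sim <- simulate_experiment(cfg)
  flagged_gene <- sim$truth$gene[sim$truth$is_target][1]
  rep <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                       sim$pulldown_cancer, sim$predictions,
                                       annotation_genes = flagged_gene))
  plain <- suppressWarnings(run_pipeline(sim$stable, sim$pulldown_normal,
                                         sim$pulldown_cancer, sim$predictions))
  expect_identical(rep$final_targets, plain$final_targets)
  td <- tidy(rep)
  expect_true("flagged" %in% names(td))
  expect_true(td$flagged[td$gene == flagged_gene])
})

test_that("stage failures name the failing stage", {
  cfg <- sim_config(n_genes = 100, n_targets = 5, seed = 6)
  sim <- simulate_experiment(cfg)
  bad_stable <- dplyr::rename(sim$stable, weird_1 = control_1)
  expect_error(
    suppressWarnings(run_pipeline(bad_stable, sim$pulldown_normal,
                                  sim$pulldown_cancer, sim$predictions)),
    "de_screen"
  )
})
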