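test_that("select_markers applies the peak, floor and specificity rules", {
  expr <- rbind(peaked = c(1, 1, 20, 1, 1),
                flat = c(10, 10, 10, 10, 10),
                weak = c(1, 1, 4, 1, 1),         # unique peak below floor
                broad = c(1, 14, 20, 1, 1))      # peak < 1.5 x second
  colnames(expr) <- paste0("S", 1:5)
  mk <- select_markers(expr, min_expression = 5, specificity_fold = 1.5)
  expect_equal(mk$gene_id, "peaked")
  expect_equal(mk$peak_stage, "S3")
  expect_equal(mk$peak_rpkm, 20)
  expect_equal(mk$second_rpkm, 1)
  # stages without markers are recorded as a warning, not an error
  expect_match(attr(mk, "warnings"), "S1")
  expect_error(select_markers(expr[, 1, drop = FALSE]), "2 calibration stages")
})

test_that("markers of a synthetic atlas are recovered with correct stages", {
  sim <- simulate_atlas(2000, markers_per_stage = 50, dispersion = 0.05,
                        library_size = 2e6, seed = 13)
  mk <- select_markers(calibration_rpkm(sim))
  truth <- sim$truth$marker_assignment
  hit <- match(names(truth), mk$gene_id)
  recovered <- !is.na(hit) & mk$peak_stage[hit] == truth
  expect_gte(mean(recovered), 0.95)
})

test_that("score_sample is self-consistent on calibration columns", {
  sim <- simulate_atlas(800, markers_per_stage = 40, seed = 17)
  base <- sim$truth$base_expression
  mk <- select_markers(base)
  for (k in c(1, 3, 5)) {
    pred <- score_sample(mk, base, base[, k])
    expect_identical(unique(unname(pred$per_marker_score)), as.integer(k))
    expect_identical(pred$mean_score, as.numeric(k))
  }
  # density integrates to ~1 on its grid
  pred <- score_sample(mk, base, base[, 2])
  area <- sum(pred$density$values) * diff(pred$density$grid[1:2])
  expect_lt(abs(area - 1), 0.05)
  expect_error(score_sample(mk, base, base[1:10, 2]), "absent from unknown")
})

test_that("interpolated unknowns at 2.5 score between the flanking stages", {
  sim <- simulate_atlas(2000, markers_per_stage = 100, seed = 1)
  cal <- calibration_rpkm(sim)
  mk <- select_markers(cal, specificity_fold = 2)
  expect_gte(nrow(mk), 200)
  scores <- vapply(1:5, function(s) {
    u <- simulate_unknown(sim$truth, 2.5, "interpolated", seed = s)
    score_sample(mk, cal, rpkm_vec(u$counts, sim$truth$gene_lengths))$mean_score
  }, numeric(1))
  expect_true(all(scores >= 2.2 & scores <= 2.8))
})

test_that("mixed-state unknowns produce multi-peak score densities", {
  sim <- simulate_atlas(2000, markers_per_stage = 100, seed = 1)
  cal <- calibration_rpkm(sim)
  mk <- select_markers(cal, specificity_fold = 2)
  for (s in 1:3) {
    u <- simulate_unknown(sim$truth, 2.5, "mixed", seed = s)
    pred <- score_sample(mk, cal, rpkm_vec(u$counts, sim$truth$gene_lengths))
    expect_gte(density_peaks(pred$density), 2)
    big <- density_maxima(pred$density, min_height = 0.25)
    expect_true(any(abs(big - 2) < 0.5))
    expect_true(any(abs(big - 3) < 0.5))
  }
})

test_that("similarity profiles scale to [0, 1] with the matching stage at 1", {
  sim <- simulate_atlas(1500, markers_per_stage = 60, seed = 23)
  cal <- calibration_rpkm(sim, 1)
  bnd <- calibration_rpkm(sim, 2)
  mk <- select_markers(cal, specificity_fold = 2)
  stage_preds <- lapply(1:5, function(k)
    score_sample(mk, cal, bnd[, k], sample_id = colnames(bnd)[k]))

  # unknown identical to the held-out replicate of stage 3
  self <- similarity_profile(stage_preds[[3]], stage_preds)
  expect_equal(self$scaled_similarity[3], 1)
  expect_true(all(self$scaled_similarity >= 0 & self$scaled_similarity <= 1))
  # distinct P-values: exactly one 1 and one 0
  u <- simulate_unknown(sim$truth, 3.5, "interpolated", seed = 31)
  pred <- score_sample(mk, cal, rpkm_vec(u$counts, sim$truth$gene_lengths))
  prof <- similarity_profile(pred, stage_preds)
  if (length(unique(prof$p_value)) == 5) {
    expect_equal(sum(prof$scaled_similarity == 1), 1)
    expect_equal(sum(prof$scaled_similarity == 0), 1)
  }
  expect_true(which.max(prof$scaled_similarity) %in% c(3, 4))
})

test_that("predict_batch orchestrates the full workflow", {
  sim <- simulate_atlas(1200, markers_per_stage = 50, replicates = 2, seed = 37)
  # unknowns: three samples copied around stage profiles
  u1 <- simulate_unknown(sim$truth, 2.0, "interpolated", seed = 41)
  u2 <- simulate_unknown(sim$truth, 3.5, "interpolated", seed = 42)
  u3 <- simulate_unknown(sim$truth, 4.5, "mixed", seed = 43)
  ucounts <- cbind(u1 = u1$counts, u2 = u2$counts, u3 = u3$counts)
  umeta <- data.frame(sample = c("u1", "u2", "u3"),
                      genotype = c("g1", "g2", "g3"), tissue = "meristem",
                      stage = "unknown", replicate = 1)
  unknowns <- count_matrix(ucounts, sim$counts$gene_lengths, umeta)
  rep_names <- c("g1.meristem.unknown", "g2.meristem.unknown",
                 "g3.meristem.unknown")

  report <- predict_batch(sim$counts, unknowns, specificity_fold = 2)
  expect_s3_class(report, "ddi_report")
  expect_setequal(names(report$unknowns), rep_names)
  for (id in rep_names) {
    u <- report$unknowns[[id]]
    expect_true(u$prediction$mean_score >= 1 && u$prediction$mean_score <= 5)
    expect_equal(nrow(u$similarity), 5)
  }
  # JSON report round trip
  path <- file.path(tempdir(), "report.json")
  write_ddi_report(report, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed$unknowns, rep_names, ignore.order = TRUE)
  expect_equal(parsed$unknowns[[1]]$mean_score,
               report$unknowns[[1]]$prediction$mean_score)

  # an unknown equal to the boundary replicate's stage-3 column reproduces
  # that replicate's own prediction
  md <- sim$counts$metadata
  col3 <- md$sample[md$replicate == 2 & md$stage == "LVM"]
  copycat <- count_matrix(
    matrix(sim$counts$counts[, col3], dimnames = list(rownames(sim$counts$counts), "cp")),
    sim$counts$gene_lengths,
    data.frame(sample = "cp", genotype = "cp", tissue = "meristem",
               stage = "unknown", replicate = 1))
  rep2 <- predict_batch(sim$counts, copycat, specificity_fold = 2)
  expect_lt(abs(rep2$unknowns[[1]]$prediction$mean_score -
                rep2$stage_predictions[["LVM"]]$mean_score), 0.05)
})

test_that("two calibration points are enough for leaf-style staging", {
  sim <- simulate_atlas(600, stage_labels = c("early", "late"),
                        markers_per_stage = 40, seed = 47)
  u <- simulate_unknown(sim$truth, 1.5, "interpolated", seed = 48)
  ucm <- count_matrix(matrix(u$counts, dimnames = list(names(u$counts), "u")),
                      sim$counts$gene_lengths,
                      data.frame(sample = "u", genotype = "het",
                                 tissue = "leaf", stage = "unknown",
                                 replicate = 1))
  report <- predict_batch(sim$counts, ucm, specificity_fold = 2)
  sc <- report$unknowns[[1]]$prediction$mean_score
  expect_true(sc >= 1 && sc <= 2)
})

test_that("a midway heterozygote profile scores between its parents", {
  sim <- simulate_atlas(2000, markers_per_stage = 100, seed = 1)
  cal <- calibration_rpkm(sim)
  mk <- select_markers(cal, specificity_fold = 2)
  score_at <- function(pos, seed) {
    u <- simulate_unknown(sim$truth, pos, "interpolated", seed = seed)
    score_sample(mk, cal, rpkm_vec(u$counts, sim$truth$gene_lengths))$mean_score
  }
  ok <- vapply(1:100, function(s) {
    normal <- score_at(4.0, 300 + 3 * s)
    delayed <- score_at(2.0, 301 + 3 * s)
    het <- score_at(3.0, 302 + 3 * s)
    het > min(normal, delayed) && het < max(normal, delayed)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
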