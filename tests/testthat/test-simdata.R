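test_that("simulate_atlas honours its contracts and determinism", {
  sim <- simulate_atlas(600, markers_per_stage = 20, seed = 42)
  expect_equal(length(sim$truth$marker_assignment), 100)
  expect_equal(unname(table(sim$truth$marker_assignment)["TM"]), 20)
  # marker truth: strictly maximal at the assigned stage
  for (g in names(sim$truth$marker_assignment)[seq(1, 100, 7)]) {
    prof <- sim$truth$base_expression[g, ]
    expect_equal(names(which.max(prof)), unname(sim$truth$marker_assignment[g]))
    expect_true(max(prof[-which.max(prof)]) < max(prof))
  }
  expect_true(all(sim$counts$gene_lengths >= 300 &
                  sim$counts$gene_lengths <= 5000))
  # determinism
  sim2 <- simulate_atlas(600, markers_per_stage = 20, seed = 42)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$truth, sim2$truth)

  expect_error(simulate_atlas(10, markers_per_stage = 5, seed = 1),
               "exceeds n_genes")
  expect_error(simulate_atlas(100, replicates = 1, seed = 1), "replicates")
  expect_error(simulate_atlas(-5, seed = 1), "positive")
})

test_that("zero dispersion gives Poisson-like counts (variance ~ mean)", {
  sim <- simulate_atlas(3000, markers_per_stage = 10, replicates = 2,
                        dispersion = 0, seed = 9)
  mu <- sim$truth$base_expression[, "EVM"] *
    (sim$counts$gene_lengths / 1e3) * 2  # library 2e6
  y <- sim$counts$counts[, c("EVM_r1", "EVM_r2")]
  # pooled standardized residuals should have unit variance under Poisson
  z <- (y - mu) / sqrt(pmax(mu, 1e-9))
  expect_lt(abs(mean(z^2) - 1), 0.1)
})

test_that("simulate_unknown interpolates means and respects bounds", {
  sim <- simulate_atlas(400, markers_per_stage = 10, seed = 5)
  expect_error(simulate_unknown(sim$truth, 0.5, seed = 1), "position")
  expect_error(simulate_unknown(sim$truth, 5.4, seed = 1), "position")
  # integer position: means equal the stage profile exactly -> with zero
  # dispersion and a huge library the RPKM profile converges on the stage
  # column
  sim0 <- simulate_atlas(400, markers_per_stage = 10, dispersion = 0, seed = 5)
  u <- simulate_unknown(sim0$truth, 3, "interpolated", library_size = 5e8,
                        seed = 6)
  ux <- rpkm_vec(u$counts, sim0$truth$gene_lengths)
  ref <- sim0$truth$base_expression[, 3]
  keep <- ref > 1
  # a gene panel is not a whole transcriptome, so recovered RPKM carries a
  # constant per-sample scale factor; the profile shape must converge
  dev <- log2(ux[keep] / ref[keep])
  expect_lt(stats::median(abs(dev - stats::median(dev))), 0.1)
  # mixed mode at an integer position is the same profile (lambda = 0)
  u2a <- simulate_unknown(sim$truth, 3, "mixed", seed = 7)
  u2b <- simulate_unknown(sim$truth, 3, "interpolated", seed = 7)
  expect_identical(u2a$counts, u2b$counts)
})

test_that("simulate_trio realizes category mean orderings and determinism", {
  sim <- simulate_trio(1200, category_fractions = rep(0.02, 12),
                       effect_size = 4, replicates = 2, dispersion = 0.05,
                       seed = 21)
  truth <- sim$truth
  map <- gene_action_categories()
  dir_of <- function(a, b) if (a > b * 1.01) "up" else if (b > a * 1.01) "down" else "ns"
  cat_genes <- names(truth$category_per_gene)[!is.na(truth$category_per_gene)]
  for (g in cat_genes[seq(1, length(cat_genes), by = 9)]) {
    k <- truth$category_per_gene[g]
    m <- truth$mean_expression[g, ]          # (P1, P2, H)
    expect_equal(dir_of(m[3], m[1]), map$call_hp1[k], info = g)
    expect_equal(dir_of(m[3], m[2]), map$call_hp2[k], info = g)
    expect_equal(dir_of(m[1], m[2]), map$call_p1p2[k], info = g)
    expect_equal(unname(truth$class_per_gene[g]), map$class[k])
  }
  # null genes: equal means
  nulls <- names(truth$category_per_gene)[is.na(truth$category_per_gene)]
  expect_true(all(truth$mean_expression[nulls, 1] ==
                  truth$mean_expression[nulls, 2]))

  sim2 <- simulate_trio(1200, category_fractions = rep(0.02, 12),
                        effect_size = 4, replicates = 2, dispersion = 0.05,
                        seed = 21)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  expect_error(simulate_trio(100, category_fractions = rep(0.1, 12), seed = 1),
               "more than 1")
  expect_error(simulate_trio(100, effect_size = 2, seed = 1), "effect_size")
})

test_that("simulate_architecture follows the sympodial decay model", {
  pars <- list(sp = architecture_params(c(7, 9), c(3, 2, 1)),
               het = architecture_params(c(7, 9), c(3, 2, 1), delay_shift = 1))
  pt1 <- simulate_architecture(pars, n_plants = 1, seed = 2)
  expect_equal(nrow(pt1), 2)                       # one row per genotype
  pt <- simulate_architecture(pars, n_plants = 200, seed = 3)
  expect_true(all(pt$inflorescences == pt$sympodial_units + 1))
  expect_true(all(pt$leaves_primary >= 7 & pt$leaves_primary <= 9))
  # delayed genotype has strictly larger expected sympodial-unit count
  m <- tapply(pt$sympodial_units, pt$genotype, mean)
  expect_gt(m["het"], m["sp"])
  # indeterminate cap
  wt <- list(wt = architecture_params(c(7, 9), c(3, 3), max_units = 10))
  ptw <- simulate_architecture(wt, n_plants = 50, seed = 4)
  expect_true(all(ptw$sympodial_units <= 10))
  expect_gt(mean(ptw$sympodial_units == 10), 0.5)

  expect_error(simulate_architecture(list(), 5), "empty")
  expect_error(architecture_params(c(0, 3)), "lower bound")
  expect_error(architecture_params(delay_shift = -1), "delay_shift")
})

test_that("identical architecture params give null Wilcoxon behaviour", {
  pars <- list(a = architecture_params(), b = architecture_params())
  pvals <- vapply(1:100, function(s) {
    pt <- simulate_architecture(pars, n_plants = 30, seed = s)
    wilcoxon_rank_sum(pt$sympodial_units[pt$genotype == "a"],
                      pt$sympodial_units[pt$genotype == "b"])$p_value
  }, numeric(1))
  expect_gte(mean(pvals >= 0.05), 0.9)
})

test_that("mean maturation score is monotone in simulated position", {
  sim <- simulate_atlas(1500, markers_per_stage = 60, seed = 11)
  cal <- calibration_rpkm(sim)
  mk <- select_markers(cal, specificity_fold = 2)
  positions <- seq(1, 5, by = 0.5)
  scores <- vapply(positions, function(p) {
    u <- simulate_unknown(sim$truth, p, "interpolated", seed = 500 + round(10 * p))
    score_sample(mk, cal, rpkm_vec(u$counts, sim$truth$gene_lengths))$mean_score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})
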