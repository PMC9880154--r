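make_cohort_profiles <- function(animal_sd = 0.04, seed = 1,
                                 design = default_cohort_design(animal_sd)) {
  p <- make_promoter_sequence(seed = 11)
  catalog <- assign_regions(p$catalog)
  tr <- simulate_methylome(catalog, design, seed = seed)
  data.frame(sample_id = tr$sample_id, stage = tr$stage, cpg_id = tr$cpg_id,
             region_id = tr$region_id, percent = 100 * tr$true_fraction,
             flag = "ok", stringsAsFactors = FALSE)
}

test_that("site-wise Welch tests match the textbook formula", {
  x <- c(42.1, 44.8, 41.2)
  y <- c(47.9, 46.5, 49.3)
  prof <- data.frame(
    sample_id = paste0(rep(c("A", "B"), each = 3), 1:3),
    stage = rep(c("PND14", "PND35"), each = 3),
    cpg_id = "CpG1", region_id = 2, percent = c(x, y), flag = "ok")
  res <- sitewise_tests(prof)
  oracle <- oracle_welch(x, y)
  expect_equal(res$t, unname(oracle["t"]), tolerance = 1e-10)
  expect_equal(res$p, unname(oracle["p"]), tolerance = 1e-10)
})

test_that("site-wise tests handle identical and degenerate groups", {
  prof <- data.frame(
    sample_id = paste0(rep(c("A", "B"), each = 3), 1:3),
    stage = rep(c("PND14", "PND35"), each = 3),
    cpg_id = "CpG1", region_id = 1, percent = rep(50, 6), flag = "ok")
  res <- sitewise_tests(prof)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  prof$percent <- rep(c(40, 60), each = 3)  # zero variance, unequal means
  res2 <- sitewise_tests(prof)
  expect_equal(res2$p, 0)
  expect_true(res2$degenerate)
  # a site without coverage in one stage is skipped and reported
  prof$flag[4:6] <- "insufficient"
  prof$percent[4:6] <- NA
  res3 <- sitewise_tests(prof)
  expect_equal(nrow(res3), 0)
  expect_identical(attr(res3, "skipped"), "CpG1")
})

test_that("Bonferroni adjustment is a capped multiplication", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- c(0.001, 0.01, 0.04)
  expect_true(all(diff(bonferroni(sort(p), 3)) >= 0))
})

test_that("region ANOVA detects the planted islet-region stage effect", {
  prof <- make_cohort_profiles(seed = 8)
  res <- region_anova(prof)
  r2 <- res$omnibus[res$omnibus$region_id == 2, ]
  expect_true(r2$evaluable)
  expect_lt(r2$p, 0.05)
  ph <- res$posthoc[res$posthoc$region_id == 2, ]
  d35 <- ph[ph$stage_a == "PND14" & ph$stage_b == "PND35", ]
  expect_lt(d35$diff, 0)            # pre-pubertal lower
  expect_lt(abs(d35$diff + 5), 3)   # ~5 percentage points
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  # one-way mode on animal means agrees on direction
  res1 <- region_anova(prof, mode = "oneway")
  expect_lt(res1$omnibus$p[res1$omnibus$region_id == 2], 0.05)
})

test_that("region ANOVA marks sparse regions not evaluable", {
  prof <- make_cohort_profiles(seed = 9)
  keep1 <- prof$cpg_id[prof$region_id == 1][1]
  prof_sparse <- prof[prof$region_id != 1 | prof$cpg_id == keep1, ]
  res <- region_anova(prof_sparse)
  r1 <- res$omnibus[res$omnibus$region_id == 1, ]
  expect_false(r1$evaluable)
  expect_true(is.na(r1$p))
  # post-hoc still runs on the available animal means
  expect_equal(sum(res$posthoc$region_id == 1), 3)
})

test_that("null cohorts reject near the nominal rate", {
  design <- default_cohort_design()
  null_rm <- design$region_means
  null_rm["PND35", ] <- null_rm["PND14", ]
  null_rm["PND56", ] <- null_rm["PND14", ]
  design_null <- cohort_design(design$stages, 3L, null_rm, design$animal_sd,
                               design$expression_fold)
  rejected <- 0
  n_cohorts <- 120
  for (s in seq_len(n_cohorts)) {
    prof <- make_cohort_profiles(seed = 5000 + s, design = design_null)
    res <- region_anova(prof)
    rejected <- rejected + (res$omnibus$p[res$omnibus$region_id == 2] < 0.05)
  }
  expect_lt(abs(rejected / n_cohorts - 0.05), 0.05)
})

test_that("delta-delta-Ct reproduces closed forms and the fold change", {
  expect_equal(2^-0, 1)
  design <- default_cohort_design()
  ct <- simulate_qpcr(design, replicates = 3, ct_noise_sd = 0, seed = 1)
  res <- ddct_expression(ct, calibrator_stage = "PND14")
  # calibrator ddCt = 0 -> relative quantity exactly 1
  expect_equal(res$samples$rq[res$samples$stage == "PND14"], rep(1, 3))
  # fold 0.3 at puberty: ddCt = log2(1/0.3) ~ 1.737, RQ = 0.30
  dd35 <- unique(round(res$samples$ddct[res$samples$stage == "PND35"], 10))
  expect_equal(dd35, round(log2(1 / 0.3), 10))
  expect_equal(res$samples$rq[res$samples$stage == "PND35"], rep(0.3, 3),
               tolerance = 1e-10)
  expect_equal(res$stages$mean_rq[res$stages$stage == "PND35"], 0.3,
               tolerance = 1e-10)
})

test_that("expression analysis is shift invariant and flags missing wells", {
  design <- default_cohort_design()
  ct <- simulate_qpcr(design, seed = 3)
  res <- ddct_expression(ct)
  ct_shifted <- ct
  ct_shifted$ct <- ct$ct + 3.7  # plate-wide shift hits both genes equally
  res_shifted <- ddct_expression(ct_shifted)
  expect_equal(res$samples$rq, res_shifted$samples$rq, tolerance = 1e-12)
  expect_true(res$anova_p < 0.05)
  expect_equal(nrow(res$tukey), 3)
  # a sample lacking reference wells is dropped with a warning
  ct_miss <- ct[!(ct$sample_id == "PND35_2" & ct$gene == "reference"), ]
  expect_warning(res_miss <- ddct_expression(ct_miss), "PND35_2")
  expect_false("PND35_2" %in% res_miss$samples$sample_id)
})

test_that("the simulated cohort shows the ~70% expression drop at puberty", {
  design <- default_cohort_design()
  ct <- simulate_qpcr(design, seed = 21)
  res <- ddct_expression(ct, calibrator_stage = "PND14")
  drop35 <- 1 - res$stages$mean_rq[res$stages$stage == "PND35"]
  drop56 <- 1 - res$stages$mean_rq[res$stages$stage == "PND56"]
  expect_gt(drop35, 0.5)
  expect_gt(drop56, 0.5)  # stays low after puberty
})

test_that("region-expression correlation matches the covariance oracle", {
  # perfectly anti-linear pairs give r = -1
  prof <- data.frame(sample_id = paste0("s", 1:4), stage = "X",
                     cpg_id = "CpG1", region_id = 1,
                     percent = c(40, 45, 50, 55), flag = "ok")
  expr <- data.frame(sample_id = paste0("s", 1:4),
                     rq = c(1.0, 0.8, 0.6, 0.4))
  res <- region_expression_correlation(prof, expr)
  expect_equal(res$r, -1)
  # hand four-point data against the covariance formula
  expr2 <- data.frame(sample_id = paste0("s", 1:4),
                      rq = c(0.9, 1.1, 0.5, 0.7))
  res2 <- region_expression_correlation(prof, expr2)
  expect_equal(res2$r, oracle_pearson(c(40, 45, 50, 55), expr2$rq),
               tolerance = 1e-12)
  # affine rescaling leaves r unchanged; negative scale flips the sign
  expr3 <- expr2
  expr3$rq <- expr2$rq * 4 + 2
  expect_equal(region_expression_correlation(prof, expr3)$r, res2$r,
               tolerance = 1e-12)
  prof_neg <- prof
  prof_neg$percent <- -2 * prof$percent + 7
  expect_equal(region_expression_correlation(prof_neg, expr2)$r, -res2$r,
               tolerance = 1e-12)
  # fewer than three pairs is not evaluable
  res_small <- region_expression_correlation(prof[1:2, ], expr[1:2, ])
  expect_true(is.na(res_small$r))
})
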