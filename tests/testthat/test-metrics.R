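test_that("detection_summary reproduces the headline operating point", {
  fx <- build_paper_fixture()
  mt <- build_match_table(fx$cohort)
  s <- suppressWarnings(detection_summary(mt))
  expect_equal(s$scan_sensitivity$numerator, 104)
  expect_equal(s$scan_sensitivity$denominator, 121)
  expect_equal(round_half_up(s$f1, 3), 0.846)
  expect_equal(round_half_up(s$scan_fppi, 3), 0.174)
  expect_equal(round_half_up(s$nodule_fp_rate, 3), 0.405)
  expect_equal(s$nodule_sensitivity$numerator, 149)
  expect_equal(s$nodule_sensitivity$denominator, 183)
  expect_equal(round_half_up(s$mean_nodules_per_nodule_scan, 2), 1.51)
  # the two F1 interval strategies both bracket the estimate
  expect_true(s$f1_ci[1] <= s$f1 && s$f1 <= s$f1_ci[2])
  sb <- suppressWarnings(detection_summary(mt, f1_method = "bootstrap",
                                           boot_reps = 200))
  expect_true(sb$f1_ci[1] <= sb$f1 && sb$f1 <= sb$f1_ci[2])
})

test_that("degenerate summaries: no true positives, undefined denominators", {
  co <- toy_cohort(with_findings = FALSE)
  mt <- build_match_table(co)
  s <- suppressWarnings(detection_summary(mt))
  expect_equal(s$f1, 0)
  expect_equal(s$scan_sensitivity$numerator, 0)
  # cohort of only nodule scans: specificity undefined, flagged not thrown
  co2 <- co
  co2$scans <- co2$scans[co2$scans$scan_id != "C", ]
  s2 <- suppressWarnings(detection_summary(build_match_table(co2)))
  expect_s3_class(s2$scan_specificity, "undefined_metric")
})

test_that("AUC equals the pairwise Mann-Whitney oracle, DeLong behaves", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes guaranteed
    scores <- round(runif(n), sample(c(1, 2), 1))  # ties likely
    rp <- roc_pr_curves(scores, truth)
    expect_equal(rp$auc_roc, oracle_auc(scores, truth), tolerance = 1e-12)
  }
  # perfect separation
  rp <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$auc_roc, 1)
  expect_equal(rp$auc_pr, 1)
  expect_equal(rp$auc_roc_se, 0)
  # all-tied scores
  rp2 <- roc_pr_curves(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(rp2$auc_roc, 0.5)
  expect_error(roc_pr_curves(1:4, rep(TRUE, 4)), "both classes")
})

test_that("DeLong interval matches an independent placement computation", {
  set.seed(21)
  scores <- round(runif(20), 2)
  truth <- c(rep(TRUE, 8), rep(FALSE, 12))
  rp <- roc_pr_curves(scores, truth)
  x <- scores[truth]; y <- scores[!truth]
  v10 <- sapply(x, function(xi) mean((y < xi) + 0.5 * (y == xi)))
  v01 <- sapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)))
  se <- sqrt(var(v10) / length(x) + var(v01) / length(y))
  expect_equal(rp$auc_roc_se, se, tolerance = 1e-9)
  expect_equal(rp$auc_roc_ci[1], max(0, rp$auc_roc - qnorm(0.975) * se),
               tolerance = 1e-9)
})

test_that("FROC staircase matches hand enumeration on a toy scan set", {
  g <- c(32L, 32L, 32L)
  nod1 <- rasterize_ellipsoid(c(8.5, 8.5, 8.5), c(2.5, 2.5, 2.5), g)
  nod2 <- rasterize_ellipsoid(c(20.5, 20.5, 20.5), c(2.5, 2.5, 2.5), g)
  fp <- rasterize_ellipsoid(c(8.5, 20.5, 8.5), c(2, 2, 2), g)
  scans <- data.frame(scan_id = c("A", "B"), contains_nodule = c(TRUE, FALSE))
  nd <- data.frame(scan_id = c("A", "A"), nodule_id = c("N1", "N2"),
                   texture = "solid", calcification = FALSE,
                   spiculation = FALSE, lobe = "middle",
                   avg_diameter_mm = 5, volume_mm3 = mask_size(nod1),
                   stringsAsFactors = FALSE)
  nd$mask <- I(list(nod1, nod2))
  fd <- data.frame(scan_id = c("A", "A", "B"), finding_id = c("F1", "F2", "F3"),
                   confidence = c(0.9, 0.5, 0.7), texture = "solid",
                   calcification = FALSE, spiculation = FALSE, lobe = "middle",
                   avg_diameter_mm = 5, volume_mm3 = 50, stringsAsFactors = FALSE)
  fd$mask <- I(list(nod1, nod2, fp))
  co <- new_cohort(scans, nd, fd)
  fr <- froc(co)
  # thresholds 0.9, 0.7, 0.5: sens 1/2, 1/2, 2/2; fp/scan 0, 1/2, 1/2
  expect_equal(fr$threshold, c(0.9, 0.7, 0.5))
  expect_equal(fr$sensitivity, c(0.5, 0.5, 1.0))
  expect_equal(fr$avg_fp_per_scan, c(0, 0.5, 0.5))
  expect_true(all(diff(fr$sensitivity) >= 0))
  expect_true(all(diff(fr$avg_fp_per_scan) >= 0))
  # nodule-containing denominator doubles the FP rate here
  fr2 <- froc(co, denominator_scans = "nodule_containing")
  expect_equal(fr2$avg_fp_per_scan, c(0, 1, 1))
  # empty findings: single (0, 0) point
  co0 <- co; co0$findings <- empty_finding_table()
  fr0 <- froc(co0)
  expect_equal(nrow(fr0), 1)
  expect_equal(fr0$sensitivity, 0)
})

test_that("subgroup sensitivities aggregate to the overall estimate", {
  fx <- build_paper_fixture()
  mt <- build_match_table(fx$cohort)
  sg <- suppressWarnings(subgroup_sensitivity(mt, fx$cohort, "age_group"))
  sg <- sg[order(sg$level), ]
  expect_equal(sg$n_detected, c(125, 24))    # 55_plus, under_55
  expect_equal(sg$n_nodules, c(152, 31))
  expect_equal(round_half_up(100 * sg$sensitivity, 1), c(82.2, 77.4))
  expect_equal(sum(sg$n_detected), 149)
  expect_equal(sum(sg$n_nodules), 183)
  # single-stratum grouping reproduces the overall proportion
  fx$cohort$scans$one <- "all"
  sg1 <- suppressWarnings(subgroup_sensitivity(mt, fx$cohort, "one"))
  expect_equal(sg1$n_detected / sg1$n_nodules, 149 / 183)
  expect_error(subgroup_sensitivity(mt, fx$cohort, "nope"), "unknown")
})

test_that("chi-square comparisons match printed significance and an oracle", {
  fx <- build_paper_fixture()
  cc <- compare_covariates(fx$cohort$scans)
  expect_lt(cc$age_group$p_value, 0.001)
  expect_equal(unname(cc$age_group$table["under_55", "nodule"]), 24)
  expect_gt(cc$sex$p_value, 0.05)
  # perfectly proportional table: statistic 0, p = 1
  sc <- data.frame(scan_id = as.character(1:40),
                   contains_nodule = rep(c(TRUE, FALSE), each = 20),
                   grp = rep(rep(c("a", "b"), each = 10), 2),
                   stringsAsFactors = FALSE)
  cp <- compare_covariates(sc, "grp")
  expect_equal(cp$grp$statistic, 0)
  expect_equal(cp$grp$p_value, 1)
  # random 3x2 table vs the direct cell-sum formula
  set.seed(7)
  sc2 <- data.frame(scan_id = as.character(1:90),
                    contains_nodule = runif(90) < 0.5,
                    grp = sample(c("x", "y", "z"), 90, replace = TRUE),
                    stringsAsFactors = FALSE)
  got <- compare_covariates(sc2, "grp")$grp
  tab <- table(sc2$grp, factor(sc2$contains_nodule, c(TRUE, FALSE)))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - expd)^2 / expd), tolerance = 1e-12)
  expect_equal(got$df, 2)
})
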