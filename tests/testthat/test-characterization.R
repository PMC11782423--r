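test_that("concordance reproduces the per-class characterization table", {
  fx <- build_paper_fixture()
  mt <- build_match_table(fx$cohort)
  tex <- concordance(mt, fx$cohort, "texture")
  ps <- tex$per_class[tex$per_class$gt_class == "part_solid", ]
  expect_equal(ps$n_detected, 42)
  expect_equal(ps$n_correct, 16)
  expect_equal(round_half_up(100 * ps$sensitivity, 1), 38.1)
  expect_equal(round_half_up(100 * ps$lower, 1), 25.0)
  expect_equal(round_half_up(100 * ps$upper, 1), 53.2)
  lob <- concordance(mt, fx$cohort, "lobe")
  ru <- lob$per_class[lob$per_class$gt_class == "right_upper", ]
  expect_equal(ru$n_correct, 49)
  expect_equal(round_half_up(100 * ru$sensitivity, 1), 98.0)
  # conservation: per-class corrects sum to the overall numerator
  for (at in c("texture", "calcification", "spiculation", "lobe")) {
    ct <- concordance(mt, fx$cohort, at)
    expect_equal(sum(ct$per_class$n_correct), ct$overall$numerator)
    expect_equal(sum(ct$per_class$n_detected), ct$overall$denominator)
    expect_equal(ct$overall$denominator, 149)
  }
})

test_that("perfect predictions give 100% concordance everywhere", {
  co <- toy_cohort(with_findings = FALSE)
  fd <- co$nodules
  names(fd)[names(fd) == "nodule_id"] <- "finding_id"
  fd$confidence <- 1
  co$findings <- fd[, c("scan_id", "finding_id", "confidence", "texture",
                        "calcification", "spiculation", "lobe",
                        "avg_diameter_mm", "volume_mm3", "mask")]
  mt <- build_match_table(co)
  for (at in c("texture", "calcification", "spiculation", "lobe")) {
    ct <- concordance(mt, co, at)
    expect_equal(ct$overall$estimate, 1)
  }
})

test_that("detected + missed counts conserve the GT marginals", {
  fx <- build_paper_fixture()
  mt <- build_match_table(fx$cohort)
  pf <- missed_vs_detected_profile(mt, fx$cohort)
  gg <- pf[pf$characteristic == "texture" & pf$level == "ground_glass", ]
  expect_equal(gg$n_missed, 17)
  expect_equal(round_half_up(gg$pct_missed, 1), 50.0)
  nd <- fx$cohort$nodules
  feats <- list(texture = table(nd$texture), lobe = table(nd$lobe))
  for (nm in names(feats)) {
    sub <- pf[pf$characteristic == nm, ]
    tot <- setNames(sub$n_detected + sub$n_missed, sub$level)
    for (lev in names(feats[[nm]]))
      expect_equal(unname(tot[lev]), unname(feats[[nm]][lev]))
  }
  expect_equal(sum(pf$n_detected[pf$characteristic == "diameter"]), 149)
  expect_equal(sum(pf$n_missed[pf$characteristic == "volume"]), 34)
})

test_that("MAE strata: hand computation and invariances", {
  co <- toy_cohort(with_findings = FALSE)
  # three matched pairs with |errors| 1, 2, 3 mm: build via identity masks
  g <- c(24L, 24L, 24L)
  m3 <- rasterize_ellipsoid(c(12.5, 17.5, 12.5), c(2.2, 2.2, 2.2), g)
  meas <- measure_nodule(m3)
  co$nodules <- rbind(co$nodules, data.frame(
    scan_id = "C", nodule_id = "N1", texture = "solid", calcification = FALSE,
    spiculation = FALSE, lobe = "middle",
    avg_diameter_mm = meas$avg_diameter_mm, volume_mm3 = meas$volume_mm3,
    mask = I(list(m3)), stringsAsFactors = FALSE))
  co$scans$contains_nodule[co$scans$scan_id == "C"] <- TRUE
  fd <- co$nodules
  names(fd)[names(fd) == "nodule_id"] <- "finding_id"
  fd$confidence <- 1
  fd$avg_diameter_mm <- fd$avg_diameter_mm + c(1, -2, 3)
  co$findings <- fd[, c("scan_id", "finding_id", "confidence", "texture",
                        "calcification", "spiculation", "lobe",
                        "avg_diameter_mm", "volume_mm3", "mask")]
  mt <- build_match_table(co)
  mae <- suppressWarnings(mae_stratified(mt, co, "diameter"))
  ov <- mae[mae$stratum == "overall", ]
  expect_equal(ov$mae, 2)
  hw <- qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(ov$lower, 2 - hw)
  expect_equal(ov$upper, 2 + hw)
  # sign flip of all errors leaves MAE unchanged; MAE >= |bias|
  fd2 <- co$findings
  fd2$avg_diameter_mm <- co$nodules$avg_diameter_mm - c(1, -2, 3)
  co2 <- co; co2$findings <- fd2
  mae2 <- suppressWarnings(mae_stratified(build_match_table(co2), co2, "diameter"))
  expect_equal(mae2$mae[mae2$stratum == "overall"], 2)
  ba <- bland_altman_pairs(mt, co, "diameter")
  expect_gte(ov$mae, abs(ba$bias) - 1e-12)
  # identical predictions: MAE 0 everywhere
  fd3 <- co$findings
  fd3$avg_diameter_mm <- co$nodules$avg_diameter_mm
  co3 <- co; co3$findings <- fd3
  mae3 <- suppressWarnings(mae_stratified(build_match_table(co3), co3, "diameter"))
  expect_true(all(mae3$mae == 0))
})

test_that("bland_altman closed-form cases and antisymmetry", {
  ba <- bland_altman(c(1, 2, 3), c(0, 2, 4))  # d = -1, 0, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -qnorm(0.975))
  expect_equal(ba$loa_upper, qnorm(0.975))
  tq <- qt(0.975, 2)
  expect_equal(ba$ci_bias, c(-tq / sqrt(3), tq / sqrt(3)))
  se_loa <- 1 * sqrt(1 / 3 + qnorm(0.975)^2 / 4)
  expect_equal(ba$ci_loa_upper, qnorm(0.975) + c(-1, 1) * tq * se_loa)
  # identical arrays: bias 0, LoA collapse
  ba0 <- bland_altman(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  # swapping the roles negates bias and mirrors the limits
  set.seed(4)
  gt <- runif(30, 4, 10); pr <- gt + rnorm(30, 0.5, 1)
  a <- bland_altman(gt, pr); b <- bland_altman(pr, gt)
  expect_equal(b$bias, -a$bias)
  expect_equal(b$loa_lower, -a$loa_upper)
  expect_equal(b$loa_upper, -a$loa_lower)
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("simulated size noise is recovered through the agreement analysis", {
  cfg <- synthetic_config(n_scans = 250, seed = 77)
  co <- generate_cohort(cfg)
  co$findings <- simulate_cad(co, detector_profile(), seed = 78)
  mt <- build_match_table(co)
  ba <- bland_altman_pairs(mt, co, "diameter")
  # configured bias 0.47 mm with sd 1.24: n ~ 130 pairs, 3 se margin
  expect_lt(abs(ba$bias - 0.47), 3 * 1.24 / sqrt(ba$n) + 1e-9)
  mae <- suppressWarnings(mae_stratified(mt, co, "diameter"))
  ov <- mae[mae$stratum == "overall", ]
  # folded-normal mean of N(0.47, 1.24^2)
  mu <- 0.47; s <- 1.24
  fold <- s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) + mu * (1 - 2 * pnorm(-mu / s))
  expect_lt(abs(ov$mae - fold), 0.35)
})
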