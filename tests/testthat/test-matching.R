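# small helper: one-scan finding/nodule frames from explicit masks
.frames <- function(fmasks, nmasks, conf = NULL) {
  f <- data.frame(finding_id = sprintf("F%d", seq_along(fmasks)),
                  confidence = if (is.null(conf)) rep(0.5, length(fmasks)) else conf)
  f$mask <- I(fmasks)
  n <- data.frame(nodule_id = sprintf("N%d", seq_along(nmasks)))
  n$mask <- I(nmasks)
  list(f = f, n = n)
}

test_that("the 10% overlap rule decides TP vs FP+FN", {
  g <- c(32L, 32L, 32L)
  nod <- voxel_mask(as.matrix(expand.grid(0:9, 0:1, 0:1)), g)  # 40 voxels
  # shift along x by 31 voxels of 40 shared columns... use explicit overlaps:
  hit <- voxel_mask(as.matrix(expand.grid(7:16, 0:1, 0:1)), g)   # inter 12, union 68
  expect_gt(iou3d(nod, hit), 0.10)
  miss <- voxel_mask(as.matrix(expand.grid(9:18, 0:1, 0:1)), g)  # inter 4, union 76
  expect_lt(iou3d(nod, miss), 0.10)
  fr <- .frames(list(hit), list(nod))
  r <- match_scan(fr$f, fr$n)
  expect_equal(nrow(r$pairs), 1)
  expect_length(r$fp_findings, 0)
  expect_length(r$fn_nodules, 0)
  fr2 <- .frames(list(miss), list(nod))
  r2 <- match_scan(fr2$f, fr2$n)
  expect_equal(nrow(r2$pairs), 0)
  expect_equal(r2$fp_findings, "F1")
  expect_equal(r2$fn_nodules, "N1")
})

test_that("two findings over one nodule: best overlap wins, other is FP", {
  g <- c(32L, 32L, 32L)
  nod <- voxel_mask(as.matrix(expand.grid(0:9, 0:0, 0:0)), g)   # 10 voxels
  good <- voxel_mask(as.matrix(expand.grid(2:9, 0:0, 0:0)), g)  # iou 8/10
  weak <- voxel_mask(as.matrix(expand.grid(6:12, 0:0, 0:0)), g) # iou 4/13
  fr <- .frames(list(weak, good), list(nod))
  r <- match_scan(fr$f, fr$n)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$finding_id, "F2")
  expect_equal(r$fp_findings, "F1")
  ob <- oracle_assignment(rbind(iou3d(weak, nod), iou3d(good, nod)), 0.10)
  expect_equal(nrow(r$pairs), ob$card)
  expect_equal(sum(r$pairs$iou), ob$tot)
})

test_that("overlap_over_finding criterion implements the literal volume reading", {
  g <- c(32L, 32L, 32L)
  nod <- voxel_mask(as.matrix(expand.grid(0:19, 0:4, 0:4)), g)   # 500 voxels
  # small finding fully inside the nodule: IoU tiny, overlap/finding = 1
  f <- voxel_mask(as.matrix(expand.grid(0:1, 0:1, 0:1)), g)      # 8 voxels
  expect_lt(iou3d(f, nod), 0.10)
  fr <- .frames(list(f), list(nod))
  expect_equal(nrow(match_scan(fr$f, fr$n, match_config())$pairs), 0)
  r <- match_scan(fr$f, fr$n, match_config(criterion = "overlap_over_finding"))
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$score, 1)
})

test_that("matching equals the exhaustive oracle and partitions inputs", {
  for (seed in 1:60) {
    inst <- random_match_instance(seed)
    r <- match_scan(inst$findings, inst$nodules)
    ob <- oracle_assignment(inst$score, 0.10)
    expect_equal(nrow(r$pairs), ob$card, info = paste("seed", seed))
    expect_equal(sum(r$pairs$score), ob$tot, tolerance = 1e-9,
                 info = paste("seed", seed))
    # partition invariants
    expect_setequal(c(r$pairs$finding_id, r$fp_findings),
                    inst$findings$finding_id)
    expect_setequal(c(r$pairs$nodule_id, r$fn_nodules), inst$nodules$nodule_id)
    expect_true(all(r$pairs$score >= 0.10))
  }
})

test_that("raising the threshold never increases the number of pairs", {
  for (seed in 1:20) {
    inst <- random_match_instance(seed + 500)
    np <- vapply(c(0.05, 0.1, 0.3, 0.5, 0.8), function(t)
      nrow(match_scan(inst$findings, inst$nodules, match_config(t))$pairs),
      numeric(1))
    expect_true(all(diff(np) <= 0))
  }
})

test_that("scan classification follows the published rules", {
  co <- toy_cohort()
  mt <- build_match_table(co)
  lab <- setNames(mt$scan_labels$label, mt$scan_labels$scan_id)
  expect_equal(unname(lab["A"]), "TP")  # exact-hit finding
  expect_equal(unname(lab["B"]), "FN")  # nodule, no finding
  expect_equal(unname(lab["C"]), "FP")  # finding on a non-nodule scan
  expect_equal(mt$counts$nodule_tp, 1)
  expect_equal(mt$counts$nodule_fn, 1)
  expect_equal(mt$counts$fp_in_nonnodule_scans, 1)
  # a nodule-bearing scan flagged contains_nodule = FALSE is inconsistent
  bad <- co
  bad$scans$contains_nodule[1] <- FALSE
  expect_error(build_match_table(bad), "contains_nodule")
})

test_that("empty and identity cohorts give degenerate match tables", {
  empty <- new_cohort(data.frame(scan_id = c("X", "Y"),
                                 contains_nodule = FALSE))
  mt <- build_match_table(empty)
  expect_equal(mt$counts$nodule_tp + mt$counts$nodule_fn +
                 mt$counts$scan_fp, 0)
  expect_equal(mt$counts$scan_tn, 2)
  # findings identical to GT: no FN, all IoU 1
  co <- toy_cohort(with_findings = FALSE)
  fd <- co$nodules
  names(fd)[names(fd) == "nodule_id"] <- "finding_id"
  fd$confidence <- 1
  co$findings <- fd[, c("scan_id", "finding_id", "confidence", "texture",
                        "calcification", "spiculation", "lobe",
                        "avg_diameter_mm", "volume_mm3", "mask")]
  mt2 <- build_match_table(co)
  expect_equal(mt2$counts$nodule_fn, 0)
  expect_equal(mt2$mean_iou, 1)
})

test_that("nodule-level TP >= scan-level TP and scan TP bounded by nodule scans", {
  fx <- build_paper_fixture()
  mt <- build_match_table(fx$cohort)
  expect_gte(mt$counts$nodule_tp, mt$counts$scan_tp)
  expect_lte(mt$counts$scan_tp, mt$counts$n_nodule_scans)
})
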