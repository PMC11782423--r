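test_that("identical report and reader sets produce zero discrepancies", {
  co <- toy_cohort(with_findings = FALSE)
  r1 <- reader_set("R1", co$nodules)
  rpt <- reader_set("report", co$nodules)
  adj <- find_discrepancies(rpt, r1, co$scans$scan_id)
  expect_equal(nrow(adj$records), 0)
  expect_length(adj$discrepant_scans, 0)
  expect_setequal(adj$concordant_scans, co$scans$scan_id)
  expect_equal(nrow(adj$concordant_nodules), nrow(co$nodules))
  fin <- finalize_reference(adj, data.frame(candidate_id = character(),
                                            decision = character()),
                            co$scans$scan_id)
  expect_equal(nrow(fin$nodules), nrow(co$nodules))
  expect_equal(sum(fin$scan_flags$contains_nodule), 2)
})

test_that("a reader-only nodule on a report-negative scan becomes a record", {
  co <- toy_cohort(with_findings = FALSE)
  g <- c(24L, 24L, 24L)
  extra_mask <- rasterize_ellipsoid(c(12.5, 17.5, 12.5), c(2.2, 2.2, 2.2), g)
  meas <- measure_nodule(extra_mask)
  extra <- data.frame(scan_id = "C", nodule_id = "X1", texture = "solid",
                      calcification = FALSE, spiculation = FALSE,
                      lobe = "middle", avg_diameter_mm = meas$avg_diameter_mm,
                      volume_mm3 = meas$volume_mm3, stringsAsFactors = FALSE)
  extra$mask <- I(list(extra_mask))
  r1 <- reader_set("R1", rbind(co$nodules, extra))
  rpt <- reader_set("report", co$nodules)
  adj <- find_discrepancies(rpt, r1, co$scans$scan_id)
  expect_equal(nrow(adj$records), 1)
  expect_equal(adj$records$source, "r1_only")
  expect_equal(adj$discrepant_scans, "C")
  # accepting it flips the previously negative scan
  dec <- data.frame(candidate_id = adj$records$candidate_id, decision = "accept",
                    stringsAsFactors = FALSE)
  fin <- finalize_reference(adj, dec, co$scans$scan_id)
  expect_true(fin$scan_flags$contains_nodule[fin$scan_flags$scan_id == "C"])
  # rejecting it keeps the concordant set only
  dec$decision <- "reject"
  fin2 <- finalize_reference(adj, dec, co$scans$scan_id)
  expect_equal(nrow(fin2$nodules), nrow(co$nodules))
  expect_false(fin2$scan_flags$contains_nodule[fin2$scan_flags$scan_id == "C"])
  # undecided records are an error
  expect_error(finalize_reference(adj, dec[0, ], co$scans$scan_id), "undecided")
})

test_that("maskless report entries pair by lobe and nearest diameter", {
  co <- toy_cohort(with_findings = FALSE)
  rpt_nod <- co$nodules
  rpt_nod$mask <- I(rep(list(NULL), nrow(rpt_nod)))
  rpt <- reader_set("report", rpt_nod)
  r1 <- reader_set("R1", co$nodules)
  adj <- find_discrepancies(rpt, r1, co$scans$scan_id)
  expect_equal(nrow(adj$records), 0)
  # a maskless entry whose diameter is off by > 50% does not pair
  rpt2_nod <- rpt_nod
  rpt2_nod$avg_diameter_mm[1] <- rpt2_nod$avg_diameter_mm[1] * 2.4
  adj2 <- find_discrepancies(reader_set("report", rpt2_nod), r1,
                             co$scans$scan_id)
  expect_equal(sort(unique(adj2$records$source)), c("r1_only", "report_only"))
  expect_true(all(adj2$records$approximate[adj2$records$source == "report_only"]))
})

test_that("finalize_reference is idempotent", {
  fx <- build_paper_fixture()
  adj <- find_discrepancies(fx$report, fx$r1, fx$cohort$scans$scan_id)
  fin <- finalize_reference(adj, fx$decisions, fx$cohort$scans$scan_id)
  # re-adjudicating the finalized ground truth against itself changes nothing
  gt_set <- reader_set("gt", fin$nodules)
  adj2 <- find_discrepancies(gt_set, gt_set, fx$cohort$scans$scan_id)
  expect_equal(nrow(adj2$records), 0)
  fin2 <- finalize_reference(adj2, fx$decisions[0, ], fx$cohort$scans$scan_id)
  expect_equal(nrow(fin2$nodules), nrow(fin$nodules))
  expect_equal(fin2$scan_flags$contains_nodule, fin$scan_flags$contains_nodule)
})

test_that("cross-tab partitions the in-scope ground truth", {
  set.seed(31)
  cfg <- synthetic_config(n_scans = 60, seed = 31)
  co <- generate_cohort(cfg)
  co$findings <- simulate_cad(co, detector_profile(), seed = 32)
  mt <- build_match_table(co)
  r1 <- simulate_reader(co, reader_profile(), seed = 33)
  xt <- detection_cross_tab(co, r1, mt)
  expect_equal(sum(xt$counts), nrow(co$nodules))
  expect_equal(xt$n_nodules, nrow(co$nodules))
  for (nm in unique(xt$by_characteristic$characteristic)) {
    sub <- xt$by_characteristic[xt$by_characteristic$characteristic == nm, ]
    expect_equal(sum(sub$n_total), nrow(co$nodules))
    expect_equal(sub$n_total, sub$both + sub$only_r1 + sub$only_cad + sub$neither)
  }
  expect_error(detection_cross_tab(co, r1, mt, scope = "NOPE"), "absent")
})

test_that("perfect reader and perfect CAD put every nodule in 'both'", {
  co <- toy_cohort(with_findings = FALSE)
  fd <- co$nodules
  names(fd)[names(fd) == "nodule_id"] <- "finding_id"
  fd$confidence <- 1
  co$findings <- fd[, c("scan_id", "finding_id", "confidence", "texture",
                        "calcification", "spiculation", "lobe",
                        "avg_diameter_mm", "volume_mm3", "mask")]
  mt <- build_match_table(co)
  r1 <- reader_set("R1", co$nodules)
  xt <- detection_cross_tab(co, r1, mt)
  expect_equal(unname(xt$counts[["both"]]), nrow(co$nodules))
  rp <- reader_performance(co, r1, mt)
  expect_equal(rp$uplift$numerator, 0)
  expect_equal(rp$r1_sensitivity$estimate, 1)
})

test_that("reader_performance agrees with detection_summary internally", {
  cfg <- synthetic_config(n_scans = 80, seed = 55)
  co <- generate_cohort(cfg)
  co$findings <- simulate_cad(co, detector_profile(), seed = 56)
  mt <- build_match_table(co)
  r1 <- simulate_reader(co, reader_profile(), seed = 57)
  rp <- reader_performance(co, r1, mt)
  s <- suppressWarnings(detection_summary(mt))
  expect_equal(rp$cad_sensitivity$numerator, s$nodule_sensitivity$numerator)
  expect_equal(rp$cad_sensitivity$denominator, s$nodule_sensitivity$denominator)
})
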