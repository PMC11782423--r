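#' Deterministic validation-study fixture
#'
#' Builds, with no randomness, a small-mask cohort engineered so that the
#' whole pipeline reproduces the published validation contingency exactly:
#' 263 scans (121 nodule-containing / 142 not), 183 ground-truth nodules of
#' which CAD detects 149 and misses 34, 49 false-positive findings inside
#' nodule scans and 23 inside non-nodule scans (spread over 21 scans),
#' scan-level 104 TP / 21 FP / 17 FN / 121 TN, the detected/missed
#' characteristic marginals, the per-class characterization concordance
#' counts, a blinded reader finding 165/183 nodules with 39 false
#' positives confined to the 33 discrepant scans, and the conflicting-scan
#' cross-tab both 7 / only-reader 2 / only-CAD 12 / neither 6.
#'
#' Masks are small ellipsoids at fixed voxel-center-aligned positions on a
#' shared 64^3 grid at 1 mm; their purpose is exact contingency
#' reproduction, not anatomical realism. Recorded diameters/volumes are
#' the measured values of the rasterized masks, chosen so each nodule
#' falls in its intended <6 / 6-8 / >8 mm and <100 / 100-250 / >250 mm^3
#' bin.
#'
#' @return list: `cohort` (finalized ground truth + CAD findings),
#'   `r1` (reader [reader_set()]), `report` (report-derived
#'   [reader_set()], including 15 maskless phantom entries the arbitrator
#'   rejects), `decisions` (arbitrator decision table),
#'   `discrepant_scans`, `discrepant_nodule_scans`.
#' @export
build_paper_fixture <- function() {
  grid <- c(64L, 64L, 64L); sp <- c(1, 1, 1)
  pos <- list(n1 = c(16.5, 16.5, 32.5), n2 = c(47.5, 16.5, 32.5),
              fp1 = c(16.5, 47.5, 32.5), fp2 = c(47.5, 47.5, 32.5),
              r1fp1 = c(16.5, 16.5, 8.5), r1fp2 = c(47.5, 16.5, 8.5))
  # ellipsoid of nominal (diameter, volume): axial semi-axes d/2, z semi-axis
  # from the volume; memoized per (shape, position)
  cache <- new.env(parent = emptyenv())
  shape_mask <- function(d, V, at) {
    key <- paste(d, V, paste(at, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    semi <- c(d / 2, d / 2, 3 * V / (pi * d^2))
    m <- rasterize_ellipsoid(at, semi, grid, sp)
    cache[[key]] <- m
    m
  }

  sid <- sprintf("S%03d", 1:263)
  # scan composition: 1-45 two detected nodules; 46-87 one detected;
  # 88-104 one detected + one missed; 105-121 one missed; 122-263 none
  nodule_scans <- 1:121

  scans <- data.frame(
    scan_id = sid, contains_nodule = c(rep(TRUE, 121), rep(FALSE, 142)),
    age_group = "55_plus", sex = "female", other_abnormality = FALSE,
    machine_type = "", scan_type = "contrast", slice_thickness_mm = 1,
    stringsAsFactors = FALSE)
  scans$age_group[c(1:2, 46:60, 88:92, 105:106)] <- "under_55"   # 24 nodule scans
  scans$age_group[122:199] <- "under_55"                         # 78 non-nodule
  scans$sex[c(1:63, 122:188)] <- "male"                          # 63 / 67
  scans$other_abnormality[c(1:66, 122:180)] <- TRUE              # 66 / 59
  scans$machine_type[1:121] <- rep(c("SOMATOM Edge Plus", "SOMATOM Definition Edge",
                                     "SOMATOM Force", "SOMATOM Drive", "Others"),
                                   c(42, 27, 34, 15, 3))
  scans$machine_type[122:263] <- rep(c("SOMATOM Edge Plus", "SOMATOM Definition Edge",
                                       "SOMATOM Force", "SOMATOM Drive", "Others"),
                                     c(49, 34, 28, 29, 2))
  scans$scan_type[c(1:71, 122:217)] <- "noncontrast"             # 71 / 96

  # --- detected nodules, in scan order -------------------------------------
  det_scan <- c(rep(1:45, each = 2), 46:104)                     # 149
  det_slot <- c(rep(1:2, 45), rep(1L, 59))
  det <- data.frame(scan = det_scan, slot = det_slot)
  det$texture <- rep(TEXTURES, c(82, 42, 25))
  det$pred_texture <- det$texture
  det$pred_texture[82] <- "part_solid"                           # solid: 81/82
  det$pred_texture[99:124] <- "solid"                            # part-solid: 16/42
  det$pred_texture[143:149] <- "solid"                           # ground-glass: 18/25
  det$calcification <- rep(c(TRUE, FALSE), c(5, 144))
  det$pred_calcification <- det$calcification
  det$pred_calcification[138:149] <- TRUE                        # no: 132/144
  det$spiculation <- rep(c(TRUE, FALSE), c(8, 141))
  det$pred_spiculation <- det$spiculation
  det$pred_spiculation[7:8] <- FALSE                             # yes: 6/8
  det$pred_spiculation[126:149] <- TRUE                          # no: 117/141
  det$lobe <- rep(LOBES, c(50, 15, 34, 29, 21))
  det$pred_lobe <- det$lobe
  det$pred_lobe[50] <- "middle"                                  # RU: 49/50
  det$pred_lobe[64:65] <- "right_lower"                          # middle: 13/15
  det$pred_lobe[99] <- "left_upper"                              # RL: 33/34
  det$pred_lobe[126:128] <- "left_lower"                         # LU: 26/29
  det$pred_lobe[149] <- "right_upper"                            # LL: 20/21
  det$d <- rep(c(4.5, 4.5, 4.5, 7, 10), c(33, 35, 10, 29, 42))
  det$V <- rep(c(60, 160, 400, 400, 400), c(33, 35, 10, 29, 42))

  # --- missed nodules: scans 88-104 slot 2, scans 105-121 slot 1 -----------
  mis <- data.frame(scan = 88:121,
                    slot = rep(c(2L, 1L), c(17, 17)))
  mis$texture <- rep(TEXTURES, c(12, 5, 17))
  mis$calcification <- rep(c(TRUE, FALSE), c(3, 31))
  mis$spiculation <- rep(c(TRUE, FALSE), c(1, 33))
  mis$lobe <- rep(LOBES, c(9, 2, 2, 8, 13))
  mis$d <- rep(c(4.5, 4.5, 7, 7, 10), c(12, 9, 2, 6, 5))
  mis$V <- rep(c(60, 160, 160, 400, 400), c(12, 9, 2, 6, 5))

  make_nodules <- function(df) {
    masks <- lapply(seq_len(nrow(df)), function(i)
      shape_mask(df$d[i], df$V[i], pos[[df$slot[i]]]))
    meas <- lapply(masks, measure_nodule)
    data.frame(scan_id = sid[df$scan], nodule_id = paste0("N", df$slot),
               texture = df$texture, calcification = df$calcification,
               spiculation = df$spiculation, lobe = df$lobe,
               avg_diameter_mm = vapply(meas, `[[`, numeric(1), "avg_diameter_mm"),
               volume_mm3 = vapply(meas, `[[`, numeric(1), "volume_mm3"),
               mask = I(masks), stringsAsFactors = FALSE)
  }
  nod_det <- make_nodules(det)
  nod_mis <- make_nodules(mis)
  nodules <- rbind(nod_det, nod_mis)
  nodules <- nodules[order(nodules$scan_id, nodules$nodule_id), ]
  rownames(nodules) <- NULL

  # --- CAD findings: one TP per detected nodule (identical mask), FPs ------
  tp <- data.frame(scan_id = sid[det$scan], finding_id = paste0("F", det$slot),
                   confidence = 0.9, texture = det$pred_texture,
                   calcification = det$pred_calcification,
                   spiculation = det$pred_spiculation, lobe = det$pred_lobe,
                   avg_diameter_mm = nod_det$avg_diameter_mm,
                   volume_mm3 = nod_det$volume_mm3,
                   mask = I(nod_det$mask), stringsAsFactors = FALSE)
  fp_sphere <- function(at) shape_mask(5, 65.4, at)   # ~r 2.5 mm sphere
  fp_row <- function(scan, id, at) {
    m <- fp_sphere(at); meas <- measure_nodule(m)
    data.frame(scan_id = sid[scan], finding_id = id, confidence = 0.35,
               texture = "solid", calcification = FALSE, spiculation = FALSE,
               lobe = "middle", avg_diameter_mm = meas$avg_diameter_mm,
               volume_mm3 = meas$volume_mm3, mask = I(list(m)),
               stringsAsFactors = FALSE)
  }
  fps <- do.call(rbind, c(
    lapply(1:49, function(s) fp_row(s, "FP1", pos$fp1)),       # 49 in nodule scans
    lapply(122:123, function(s) fp_row(s, "FP1", pos$fp1)),    # 23 FPs over 21
    lapply(122:123, function(s) fp_row(s, "FP2", pos$fp2)),    #   non-nodule scans
    lapply(124:142, function(s) fp_row(s, "FP1", pos$fp1))))
  findings <- rbind(tp, fps)
  rownames(findings) <- NULL

  cohort <- new_cohort(scans, nodules, findings, validate = TRUE)

  # --- reader R1: all GT except 18, plus 39 FPs on the discrepant scans ----
  # missed by R1: detected nodules of scans 82-87 and 99-104 (12, "only CAD")
  # and the missed nodules of scans 99-104 (6, found by neither)
  r1_missed_keys <- c(paste0(sid[82:87], ":N1"), paste0(sid[99:104], ":N1"),
                      paste0(sid[99:104], ":N2"))
  key <- paste0(nodules$scan_id, ":", nodules$nodule_id)
  r1_nod <- nodules[!key %in% r1_missed_keys, , drop = FALSE]
  r1fp_row <- function(scan, id, at) {
    m <- fp_sphere(at); meas <- measure_nodule(m)
    data.frame(scan_id = sid[scan], nodule_id = id, texture = "solid",
               calcification = FALSE, spiculation = FALSE, lobe = "right_upper",
               avg_diameter_mm = meas$avg_diameter_mm,
               volume_mm3 = meas$volume_mm3, mask = I(list(m)),
               stringsAsFactors = FALSE)
  }
  disc_nodule_scans <- c(43:45, 81:87, 99:104, 120:121)  # 18 scans, 27 nodules
  disc_nonnodule_scans <- 249:263                        # 15 scans
  r1_fps <- do.call(rbind, c(
    lapply(disc_nodule_scans, function(s) r1fp_row(s, "R1FP1", pos$r1fp1)),
    lapply(disc_nonnodule_scans, function(s) r1fp_row(s, "R1FP1", pos$r1fp1)),
    lapply(disc_nonnodule_scans[1:6], function(s) r1fp_row(s, "R1FP2", pos$r1fp2))))
  r1 <- reader_set("R1", rbind(r1_nod, r1_fps))

  # --- report: GT minus the 27 discrepant-scan nodules, plus the 18 the
  # reader missed, plus 15 maskless phantom mentions the arbitrator rejects
  disc_keys <- key[nodules$scan_id %in% sid[disc_nodule_scans]]
  rpt_nod <- nodules[!key %in% disc_keys, , drop = FALSE]
  rpt_extra <- nodules[key %in% r1_missed_keys, , drop = FALSE]
  phantom <- data.frame(scan_id = sid[disc_nonnodule_scans], nodule_id = "P1",
                        texture = "solid", calcification = FALSE,
                        spiculation = FALSE, lobe = "middle",
                        avg_diameter_mm = 5, volume_mm3 = 65,
                        mask = I(rep(list(NULL), 15)), stringsAsFactors = FALSE)
  report <- reader_set("report", rbind(rpt_nod, rpt_extra, phantom))

  # --- arbitrator decisions -------------------------------------------------
  accept_report <- paste0("report_only:", sub(":", ":", r1_missed_keys))
  r1_only_true <- c(paste0(sid[c(43, 44, 45)], ":N1"), paste0(sid[c(43, 44, 45)], ":N2"),
                    paste0(sid[81], ":N1"), paste0(sid[120:121], ":N1"))
  accept_r1 <- paste0("r1_only:", r1_only_true)
  reject_ph <- paste0("report_only:", sid[disc_nonnodule_scans], ":P1")
  reject_fp <- c(paste0("r1_only:", sid[c(disc_nodule_scans, disc_nonnodule_scans)], ":R1FP1"),
                 paste0("r1_only:", sid[disc_nonnodule_scans[1:6]], ":R1FP2"))
  decisions <- data.frame(
    candidate_id = c(accept_report, accept_r1, reject_ph, reject_fp),
    decision = rep(c("accept", "reject"),
                   c(length(accept_report) + length(accept_r1),
                     length(reject_ph) + length(reject_fp))),
    stringsAsFactors = FALSE)

  list(cohort = cohort, r1 = r1, report = report, decisions = decisions,
       discrepant_scans = sid[c(disc_nodule_scans, disc_nonnodule_scans)],
       discrepant_nodule_scans = sid[disc_nodule_scans])
}
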