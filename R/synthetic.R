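#' Simulated-detector profile
#'
#' Parameterizes the imperfect CAD detector used to exercise the pipeline.
#' Defaults are the operating characteristics measured in the validation
#' study this package's evaluation procedure follows: per-texture detection
#' sensitivities 0.872 / 0.894 / 0.595 (solid / part-solid / ground-glass),
#' an overall false-positive rate of 72 findings per 263 scans, texture
#' confusion diagonal 0.988 / 0.381 / 0.720, calcification / spiculation /
#' location accuracies 0.919 / 0.826 / 0.946, diameter bias +0.47 mm
#' (sd 1.24 mm) and volume bias +61.8 mm^3 (sd 392 mm^3) - the size-noise
#' sds are back-computed from the published limits of agreement
#' ((LoA - bias) / 1.96). True-positive masks are jittered translations of
#' the ground truth: the displacement is a uniform fraction of the nodule
#' diameter, calibrated so the matched-IoU distribution has mean near 0.42
#' with support above the 0.10 matching floor.
#'
#' @param sensitivity_by_texture named numeric triple.
#' @param fp_rate_lambda Poisson mean of false positives per scan.
#' @param jitter_frac_range displacement as a fraction of diameter,
#'   `c(lo, hi)`.
#' @param confidence_tp,confidence_fp Beta shape pairs for confidence laws.
#' @param texture_confusion 3x3 row-stochastic matrix (rows = GT texture).
#' @param calcification_accuracy,spiculation_accuracy,lobe_accuracy scalars.
#' @param diameter_bias_mm,diameter_sd_mm,volume_bias_mm3,volume_sd_mm3
#'   additive size noise.
#' @return object of class `detector_profile`.
#' @export
detector_profile <- function(
    sensitivity_by_texture = c(solid = 0.872, part_solid = 0.894,
                               ground_glass = 0.595),
    fp_rate_lambda = 72 / 263,
    jitter_frac_range = c(0.08, 0.58),
    confidence_tp = c(5, 2), confidence_fp = c(2, 5),
    texture_confusion = matrix(c(0.988, 0.008, 0.004,
                                 0.550, 0.381, 0.069,
                                 0.210, 0.070, 0.720),
                               nrow = 3, byrow = TRUE,
                               dimnames = list(TEXTURES, TEXTURES)),
    calcification_accuracy = 137 / 149,
    spiculation_accuracy = 123 / 149,
    lobe_accuracy = 141 / 149,
    diameter_bias_mm = 0.47, diameter_sd_mm = 1.24,
    volume_bias_mm3 = 61.8, volume_sd_mm3 = 392) {
  stopifnot(all(sensitivity_by_texture >= 0 & sensitivity_by_texture <= 1),
            fp_rate_lambda >= 0,
            all(abs(rowSums(texture_confusion) - 1) < 1e-9))
  structure(as.list(environment()), class = "detector_profile")
}

#' Simulated-reader profile
#'
#' @param sensitivity per-nodule detection probability (default 0.902, the
#'   blinded reader's measured sensitivity 165/183).
#' @param fp_rate_lambda Poisson mean of reader false positives per scan
#'   (default 39/263).
#' @return object of class `reader_profile`.
#' @export
reader_profile <- function(sensitivity = 165 / 183, fp_rate_lambda = 39 / 263) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate_lambda >= 0)
  structure(list(sensitivity = sensitivity, fp_rate_lambda = fp_rate_lambda),
            class = "reader_profile")
}

#' Synthetic cohort configuration
#'
#' The stated world of the generator mirrors the validation cohort:
#' 121/263 of scans nodule-containing; a zero-truncated Poisson nodule
#' count (mu = 0.88976, mean 1.51) capped at 10 per scan; texture
#' marginals 94/47/42 out of 183; calcification and spiculation rates
#' 8/183 and 9/183; lobe marginals 59/17/36/37/34 out of 183; diameters
#' from a log-normal (meanlog 1.5794, sdlog 0.6023) truncated to
#' (4, 29.5) mm so the <6 / 6-8 / >8 mm bins hold about 54% / 20% / 26%
#' (the 4 mm floor keeps rasterized Feret diameters above the 3 mm nodule
#' definition at 1 mm voxels); age distributed conditionally on nodule
#' status (24/121 vs 78/142 under 55) and the remaining covariates by
#' their overall marginals. Nodules are ellipsoids (axial semi-axes d/2,
#' z semi-axis log-normally elongated, sd 0.15) placed uniformly in
#' synthetic per-lobe boxes on a 64^3 grid at 1 mm spacing. The recorded
#' `avg_diameter_mm` is the sampled diameter (the annotator's value, and
#' the axial diameter of the generating ellipsoid); `volume_mm3` is the
#' exact rasterized mask volume. The sampling floor sits at 3.05 mm so
#' every draw respects the strict 3-30 mm nodule definition.
#'
#' @param n_scans number of scans.
#' @param prevalence fraction of nodule-containing scans.
#' @param nodule_count_mu Poisson mean before zero truncation.
#' @param max_nodules_per_scan cap (study exclusion rule).
#' @param texture_marginals,lobe_marginals probability vectors (sum 1).
#' @param calcification_rate,spiculation_rate scalars.
#' @param diameter_meanlog,diameter_sdlog,diameter_range_mm diameter law.
#' @param elongation_sdlog z-axis elongation spread.
#' @param grid_shape,spacing_mm scan grid.
#' @param covariates list of covariate laws (see defaults).
#' @param detector a [detector_profile()].
#' @param reader a [reader_profile()].
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_scans = 263,
    prevalence = 121 / 263,
    nodule_count_mu = 0.8897624,
    max_nodules_per_scan = 10L,
    texture_marginals = c(solid = 94, part_solid = 47, ground_glass = 42) / 183,
    calcification_rate = 8 / 183,
    spiculation_rate = 9 / 183,
    lobe_marginals = c(right_upper = 59, middle = 17, right_lower = 36,
                       left_upper = 37, left_lower = 34) / 183,
    diameter_meanlog = 1.579431, diameter_sdlog = 0.602289,
    diameter_range_mm = c(3.05, 29.5),
    elongation_sdlog = 0.15,
    grid_shape = c(64L, 64L, 64L), spacing_mm = c(1, 1, 1),
    covariates = list(p_under55_nodule = 24 / 121,
                      p_under55_nonnodule = 78 / 142,
                      p_male = 130 / 263,
                      p_other_abnormality = 125 / 263,
                      machine_probs = c(`SOMATOM Edge Plus` = 91,
                                        `SOMATOM Definition Edge` = 61,
                                        `SOMATOM Force` = 62,
                                        `SOMATOM Drive` = 44,
                                        Others = 5) / 263,
                      p_noncontrast = 167 / 263),
    detector = detector_profile(),
    reader = reader_profile(),
    seed = 1L) {
  stopifnot(abs(sum(texture_marginals) - 1) < 1e-9,
            abs(sum(lobe_marginals) - 1) < 1e-9,
            abs(sum(covariates$machine_probs) - 1) < 1e-9,
            prevalence >= 0, prevalence <= 1, nodule_count_mu > 0,
            max_nodules_per_scan >= 1)
  if (nodule_count_mu > max_nodules_per_scan)
    stop("synthetic_config: nodule-count mean incompatible with the per-scan cap")
  structure(as.list(environment()), class = "synthetic_config")
}

# synthetic per-lobe placement boxes (mm, on the default 64 mm cube);
# deliberately schematic, not anatomical
.lobe_boxes <- function(grid_mm) {
  gx <- grid_mm[1]; gy <- grid_mm[2]; gz <- grid_mm[3]
  list(
    right_upper = rbind(c(2, 0.47 * gx), c(2, gy - 2), c(0.66 * gz, gz - 2)),
    middle      = rbind(c(2, 0.47 * gx), c(2, gy - 2), c(0.35 * gz, 0.63 * gz)),
    right_lower = rbind(c(2, 0.47 * gx), c(2, gy - 2), c(2, 0.32 * gz)),
    left_upper  = rbind(c(0.53 * gx, gx - 2), c(2, gy - 2), c(0.50 * gz, gz - 2)),
    left_lower  = rbind(c(0.53 * gx, gx - 2), c(2, gy - 2), c(2, 0.47 * gz)))
}

.sample_trunc_lnorm <- function(n, meanlog, sdlog, range) {
  lo <- stats::plnorm(range[1], meanlog, sdlog)
  hi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

.sample_ztpois <- function(n, mu, cap) {
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- 0L
    while (k == 0L) k <- stats::rpois(1, mu)
    out[i] <- min(k, cap)
  }
  out
}

# place one ellipsoid in a lobe box, avoiding voxel overlap with existing
# masks; returns a voxel_mask
.place_nodule <- function(semi, lobe, grid_shape, spacing, existing, tries = 30L) {
  box <- .lobe_boxes(grid_shape * spacing)[[lobe]]
  best <- NULL
  for (t in seq_len(tries)) {
    ctr <- vapply(1:3, function(ax) {
      lo <- max(box[ax, 1], semi[ax] + 0.6)
      hi <- min(box[ax, 2], grid_shape[ax] * spacing[ax] - semi[ax] - 0.6)
      if (lo >= hi) (box[ax, 1] + box[ax, 2]) / 2 else stats::runif(1, lo, hi)
    }, numeric(1))
    m <- tryCatch(rasterize_ellipsoid(ctr, semi, grid_shape, spacing),
                  error = function(e) NULL)
    if (is.null(m)) next
    if (is.null(best)) best <- m
    if (length(existing) == 0) return(m)
    k <- .vox_key(m$voxels, grid_shape)
    clash <- any(vapply(existing, function(e)
      any(.vox_key(e$voxels, grid_shape) %in% k), logical(1)))
    if (!clash) return(m)
  }
  best  # accept a (rare) overlap rather than fail
}

#' Generate a synthetic ground-truth cohort
#'
#' Draws scans, covariates and ellipsoid-mask nodules from the laws in a
#' [synthetic_config()]. Reproducible: the configured seed fixes every
#' byte of the result. Returns a ground-truth-only cohort (no findings);
#' feed it to [simulate_cad()] and [simulate_reader()].
#'
#' @param config a [synthetic_config()].
#' @return a validated `cad_cohort`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_scans
  ids <- sprintf("SYN%04d", seq_len(n))
  has_nod <- stats::runif(n) < config$prevalence
  cov <- config$covariates
  p_u55 <- ifelse(has_nod, cov$p_under55_nodule, cov$p_under55_nonnodule)
  scans <- data.frame(
    scan_id = ids,
    contains_nodule = has_nod,
    age_group = ifelse(stats::runif(n) < p_u55, "under_55", "55_plus"),
    sex = ifelse(stats::runif(n) < cov$p_male, "male", "female"),
    other_abnormality = stats::runif(n) < cov$p_other_abnormality,
    machine_type = sample(names(cov$machine_probs), n, replace = TRUE,
                          prob = cov$machine_probs),
    scan_type = ifelse(stats::runif(n) < cov$p_noncontrast, "noncontrast", "contrast"),
    slice_thickness_mm = 1,
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in which(has_nod)) {
    m <- .sample_ztpois(1, config$nodule_count_mu, config$max_nodules_per_scan)
    existing <- list()
    for (j in seq_len(m)) {
      texture <- sample(TEXTURES, 1, prob = config$texture_marginals)
      lobe <- sample(LOBES, 1, prob = config$lobe_marginals)
      d <- .sample_trunc_lnorm(1, config$diameter_meanlog, config$diameter_sdlog,
                               config$diameter_range_mm)
      semi <- c(d / 2, d / 2, (d / 2) * exp(stats::rnorm(1, 0, config$elongation_sdlog)))
      mask <- .place_nodule(semi, lobe, config$grid_shape, config$spacing_mm, existing)
      if (is.null(mask)) next
      existing <- c(existing, list(mask))
      meas <- measure_nodule(mask)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = ids[i], nodule_id = sprintf("N%02d", j),
        texture = texture,
        calcification = stats::runif(1) < config$calcification_rate,
        spiculation = stats::runif(1) < config$spiculation_rate,
        lobe = lobe,
        avg_diameter_mm = d,
        volume_mm3 = meas$volume_mm3,
        mask = I(list(mask)), stringsAsFactors = FALSE)
    }
  }
  nodules <- if (length(rows)) do.call(rbind, rows) else empty_nodule_table()
  scans$contains_nodule <- scans$scan_id %in% nodules$scan_id
  new_cohort(scans, nodules, validate = TRUE, strict = TRUE)
}

# jittered copy of a GT mask achieving IoU >= floor; translation by a
# uniform fraction of the diameter in a random direction
.jitter_mask <- function(mask, d_mm, frac_range, floor_iou, tries = 25L) {
  best <- NULL; best_iou <- -1
  for (t in seq_len(tries)) {
    u <- stats::runif(1, frac_range[1], frac_range[2])
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    delta <- round(u * d_mm * dir / mask$spacing_mm)
    m <- tryCatch(shift_mask(mask, delta), error = function(e) NULL)
    if (is.null(m)) next
    iou <- iou3d(m, mask)
    if (iou >= floor_iou) return(m)
    if (iou > best_iou) { best <- m; best_iou <- iou }
  }
  mask  # fall back to the unshifted mask (IoU 1); rare for sane ranges
}

.rand_other <- function(value, levels) sample(setdiff(levels, value), 1)

#' Simulate CAD output on a ground-truth cohort
#'
#' Each ground-truth nodule is detected with its texture's sensitivity; a
#' detected nodule yields a finding whose mask is a jittered translation of
#' the truth (IoU kept above the matching floor), whose categorical
#' characteristics pass through the confusion/accuracy parameters, and
#' whose sizes are the true sizes plus configured bias and noise. False
#' positives arrive per scan as Poisson counts, placed disjoint from the
#' ground truth with small spherical masks and low-mean confidences.
#'
#' @param cohort a ground-truth `cad_cohort`.
#' @param profile a [detector_profile()].
#' @param seed integer seed.
#' @param iou_floor minimal IoU a true-positive mask keeps with its nodule.
#' @return a finding table (attachable as `cohort$findings`).
#' @export
simulate_cad <- function(cohort, profile = detector_profile(), seed = 1L,
                         iou_floor = 0.10) {
  stopifnot(inherits(profile, "detector_profile"))
  set.seed(seed)
  nd <- cohort$nodules
  rows <- list()
  gt_by_scan <- split(nd$mask, nd$scan_id)
  for (i in seq_len(nrow(nd))) {
    sens <- profile$sensitivity_by_texture[[nd$texture[i]]]
    if (stats::runif(1) >= sens) next
    gt_mask <- nd$mask[[i]]
    m <- .jitter_mask(gt_mask, nd$avg_diameter_mm[i], profile$jitter_frac_range,
                      iou_floor)
    gt_tex <- nd$texture[i]
    pred_tex <- sample(TEXTURES, 1, prob = profile$texture_confusion[gt_tex, ])
    pred_cal <- if (stats::runif(1) < profile$calcification_accuracy)
      nd$calcification[i] else !nd$calcification[i]
    pred_spi <- if (stats::runif(1) < profile$spiculation_accuracy)
      nd$spiculation[i] else !nd$spiculation[i]
    pred_lobe <- if (stats::runif(1) < profile$lobe_accuracy) nd$lobe[i] else
      .rand_other(nd$lobe[i], LOBES)
    rows[[length(rows) + 1L]] <- data.frame(
      scan_id = nd$scan_id[i],
      finding_id = paste0("F-", nd$nodule_id[i]),
      confidence = stats::rbeta(1, profile$confidence_tp[1], profile$confidence_tp[2]),
      texture = pred_tex, calcification = pred_cal, spiculation = pred_spi,
      lobe = pred_lobe,
      # additive noise kept unclipped: clipping at a physical floor would
      # truncate the noise and bias the recovered agreement statistics,
      # which are linear in the differences
      avg_diameter_mm = nd$avg_diameter_mm[i] + profile$diameter_bias_mm +
        stats::rnorm(1, 0, profile$diameter_sd_mm),
      volume_mm3 = nd$volume_mm3[i] + profile$volume_bias_mm3 +
        stats::rnorm(1, 0, profile$volume_sd_mm3),
      mask = I(list(m)), stringsAsFactors = FALSE)
  }
  # false positives
  grid <- .scan_grid(cohort)
  for (s in seq_len(nrow(cohort$scans))) {
    sid <- cohort$scans$scan_id[s]
    nfp <- stats::rpois(1, profile$fp_rate_lambda)
    if (nfp == 0) next
    existing <- gt_by_scan[[sid]]
    if (is.null(existing)) existing <- list()
    for (j in seq_len(nfp)) {
      d <- stats::runif(1, 4, 8)
      lobe <- sample(LOBES, 1)
      m <- .place_nodule(rep(d / 2, 3), lobe, grid$shape, grid$spacing, existing)
      if (is.null(m)) next
      existing <- c(existing, list(m))
      meas <- measure_nodule(m)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = sid, finding_id = sprintf("FP%02d", j),
        confidence = stats::rbeta(1, profile$confidence_fp[1], profile$confidence_fp[2]),
        texture = sample(TEXTURES, 1), calcification = FALSE,
        spiculation = FALSE, lobe = lobe,
        avg_diameter_mm = meas$avg_diameter_mm, volume_mm3 = meas$volume_mm3,
        mask = I(list(m)), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_finding_table()
}

.scan_grid <- function(cohort) {
  if (nrow(cohort$nodules)) {
    m <- cohort$nodules$mask[[1]]
    list(shape = m$grid_shape, spacing = m$spacing_mm)
  } else list(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1))
}

#' Simulate the blinded reader
#'
#' Each ground-truth nodule is annotated with probability `sensitivity`
#' (the mask copied exactly); false positives arrive per scan at the
#' configured Poisson rate.
#'
#' @param cohort a ground-truth `cad_cohort`.
#' @param profile a [reader_profile()].
#' @param seed integer seed.
#' @param reader_id id for the returned [reader_set()].
#' @return a `reader_set`.
#' @export
simulate_reader <- function(cohort, profile = reader_profile(), seed = 1L,
                            reader_id = "R1") {
  stopifnot(inherits(profile, "reader_profile"))
  set.seed(seed)
  nd <- cohort$nodules
  keep <- stats::runif(nrow(nd)) < profile$sensitivity
  ann <- nd[keep, , drop = FALSE]
  if (nrow(ann)) ann$nodule_id <- paste0("R1-", ann$nodule_id)
  rows <- if (nrow(ann)) list(ann) else list()
  grid <- .scan_grid(cohort)
  gt_by_scan <- split(nd$mask, nd$scan_id)
  for (s in seq_len(nrow(cohort$scans))) {
    sid <- cohort$scans$scan_id[s]
    nfp <- stats::rpois(1, profile$fp_rate_lambda)
    if (nfp == 0) next
    existing <- gt_by_scan[[sid]]
    if (is.null(existing)) existing <- list()
    for (j in seq_len(nfp)) {
      d <- stats::runif(1, 4, 8)
      lobe <- sample(LOBES, 1)
      m <- .place_nodule(rep(d / 2, 3), lobe, grid$shape, grid$spacing, existing)
      if (is.null(m)) next
      existing <- c(existing, list(m))
      meas <- measure_nodule(m)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = sid, nodule_id = sprintf("R1FP%02d", j),
        texture = sample(TEXTURES, 1), calcification = FALSE,
        spiculation = FALSE, lobe = lobe,
        avg_diameter_mm = meas$avg_diameter_mm, volume_mm3 = meas$volume_mm3,
        mask = I(list(m)), stringsAsFactors = FALSE)
    }
  }
  nods <- if (length(rows)) do.call(rbind, rows) else empty_nodule_table()
  rownames(nods) <- NULL
  reader_set(reader_id, nods)
}
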