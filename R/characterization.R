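#' Characterization concordance on matched pairs
#'
#' For one categorical characteristic (texture, calcification, spiculation
#' or lobe), computes per ground-truth class the proportion of correctly
#' detected nodules whose predicted class agrees with the ground truth,
#' each with a Wilson interval, plus the overall agreement across all
#' matched pairs. Only matched (detected) nodules enter: missed nodules
#' have no prediction.
#'
#' @param match_table a `match_table`.
#' @param cohort the matching `cad_cohort`.
#' @param attribute one of `"texture"`, `"calcification"`, `"spiculation"`,
#'   `"lobe"`.
#' @param config a [ci_config()].
#' @return list of class `concordance_table`: `attribute`, `per_class`
#'   data.frame (`gt_class`, `n_detected`, `n_correct`, `sensitivity`,
#'   `lower`, `upper`) and `overall` (a `proportion_ci`).
#' @export
concordance <- function(match_table, cohort, attribute, config = ci_config()) {
  attribute <- match.arg(attribute, c("texture", "calcification", "spiculation", "lobe"))
  if (!attribute %in% names(cohort$findings))
    stop("concordance: findings lack attribute ", attribute)
  pr <- .joined_pairs(match_table, cohort)
  gt <- pr[[paste0("gt_", attribute)]]
  pd <- pr[[paste0("cad_", attribute)]]
  levs <- switch(attribute,
                 texture = TEXTURES, lobe = LOBES,
                 calcification = , spiculation = c(TRUE, FALSE))
  per <- NULL
  for (lev in levs) {
    sel <- gt == lev
    if (!any(sel)) next
    k <- sum(pd[sel] == lev); n <- sum(sel)
    ci <- wilson_ci(k, n, config)
    per <- rbind(per, data.frame(gt_class = as.character(lev), n_detected = n,
                                 n_correct = k, sensitivity = ci$estimate,
                                 lower = ci$lower, upper = ci$upper,
                                 stringsAsFactors = FALSE))
  }
  overall <- wilson_ci(sum(gt == pd), length(gt), config)
  structure(list(attribute = attribute, per_class = per, overall = overall),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %s (n = %d matched pairs)\n",
              x$attribute, x$overall$denominator))
  print(x$per_class, row.names = FALSE)
  cat("  overall:", format(x$overall), "\n")
  invisible(x)
}

# matched pairs joined with GT and predicted attributes / sizes
.joined_pairs <- function(match_table, cohort) {
  pr <- match_table$pairs
  nd <- cohort$nodules; fd <- cohort$findings
  ni <- match(paste(pr$scan_id, pr$nodule_id), paste(nd$scan_id, nd$nodule_id))
  fi <- match(paste(pr$scan_id, pr$finding_id), paste(fd$scan_id, fd$finding_id))
  if (anyNA(ni) || anyNA(fi))
    stop("match table references nodules/findings absent from the cohort")
  cols <- c("texture", "calcification", "spiculation", "lobe",
            "avg_diameter_mm", "volume_mm3")
  out <- pr
  for (cc in cols) {
    out[[paste0("gt_", cc)]] <- nd[[cc]][ni]
    out[[paste0("cad_", cc)]] <- fd[[cc]][fi]
  }
  out
}

.diameter_bins <- function(d) {
  cut(d, breaks = c(-Inf, 6, 8, Inf), labels = c("<6mm", "6-8mm", ">8mm"),
      right = FALSE)
}

.volume_bins <- function(v) {
  cut(v, breaks = c(-Inf, 100, 250, Inf),
      labels = c("<100mm3", "100-250mm3", ">250mm3"), right = FALSE)
}

#' Characteristic profile of detected versus missed nodules
#'
#' Tabulates each ground-truth characteristic level (texture,
#' calcification, spiculation, lobe, diameter bins <6 / 6-8 / >8 mm,
#' volume bins <100 / 100-250 / >250 mm^3) among CAD-detected (matched)
#' and missed (FN) nodules, with within-column percentages.
#'
#' @param match_table a `match_table`.
#' @param cohort the matching `cad_cohort`.
#' @return data.frame: `characteristic`, `level`, `n_detected`,
#'   `pct_detected`, `n_missed`, `pct_missed`.
#' @export
missed_vs_detected_profile <- function(match_table, cohort) {
  nd <- cohort$nodules
  key <- paste(nd$scan_id, nd$nodule_id)
  detected <- key %in% paste(match_table$pairs$scan_id, match_table$pairs$nodule_id)
  n_det <- sum(detected); n_mis <- sum(!detected)
  feats <- list(
    texture = factor(nd$texture, TEXTURES),
    calcification = factor(ifelse(nd$calcification, "yes", "no"), c("yes", "no")),
    spiculation = factor(ifelse(nd$spiculation, "yes", "no"), c("yes", "no")),
    lobe = factor(nd$lobe, LOBES),
    diameter = .diameter_bins(nd$avg_diameter_mm),
    volume = .volume_bins(nd$volume_mm3))
  out <- NULL
  for (nm in names(feats)) {
    f <- feats[[nm]]
    for (lev in levels(f)) {
      kd <- sum(detected & f == lev); km <- sum(!detected & f == lev)
      out <- rbind(out, data.frame(
        characteristic = nm, level = lev, n_detected = kd,
        pct_detected = if (n_det > 0) 100 * kd / n_det else NA_real_,
        n_missed = km,
        pct_missed = if (n_mis > 0) 100 * km / n_mis else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Stratified mean absolute size error
#'
#' Mean absolute error between predicted and ground-truth diameter (mm) or
#' volume (mm^3) over matched pairs, overall and within ground-truth size
#' strata. The interval is a t interval on the absolute errors
#' (`method = "t"`, default) or a percentile bootstrap.
#'
#' @param match_table a `match_table`.
#' @param cohort the matching `cad_cohort`.
#' @param quantity `"diameter"` or `"volume"`.
#' @param config a [ci_config()].
#' @param method `"t"` or `"bootstrap"`.
#' @param boot_reps,boot_seed bootstrap controls.
#' @return data.frame: `stratum`, `n`, `mae`, `lower`, `upper`. Strata with
#'   no pairs are omitted with a warning; single-pair strata have `NA`
#'   bounds and are flagged with a warning.
#' @export
mae_stratified <- function(match_table, cohort,
                           quantity = c("diameter", "volume"),
                           config = ci_config(), method = c("t", "bootstrap"),
                           boot_reps = 2000, boot_seed = 1L) {
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  pr <- .joined_pairs(match_table, cohort)
  col <- if (quantity == "diameter") "avg_diameter_mm" else "volume_mm3"
  gt <- pr[[paste0("gt_", col)]]
  err <- abs(pr[[paste0("cad_", col)]] - gt)
  strat <- if (quantity == "diameter") .diameter_bins(gt) else .volume_bins(gt)
  one <- function(e, label) {
    n <- length(e)
    if (n == 0) { warning("mae_stratified: empty stratum ", label, " omitted"); return(NULL) }
    mae <- mean(e)
    if (n == 1) {
      warning("mae_stratified: stratum ", label, " has a single pair; no interval")
      return(data.frame(stratum = label, n = n, mae = mae,
                        lower = NA_real_, upper = NA_real_))
    }
    if (method == "t") {
      hw <- stats::qt((1 + config$confidence_level) / 2, n - 1) * stats::sd(e) / sqrt(n)
      lo <- mae - hw; hi <- mae + hw
    } else {
      set.seed(boot_seed)
      reps <- vapply(seq_len(boot_reps),
                     function(i) mean(sample(e, n, replace = TRUE)), numeric(1))
      alpha <- 1 - config$confidence_level
      q <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2))
      lo <- q[[1]]; hi <- q[[2]]
    }
    data.frame(stratum = label, n = n, mae = mae, lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  }
  out <- one(err, "overall")
  for (lev in levels(strat)) out <- rbind(out, one(err[strat == lev], lev))
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are `predicted - ground truth`, so a positive bias means the
#' detector over-measures. Limits of agreement are `bias +/- z * sd`; the
#' bias interval is a t interval with standard error `sd / sqrt(n)`, and
#' each limit's interval uses the large-sample standard error
#' `sd * sqrt(1/n + z^2 / (2 (n - 1)))` with a t quantile.
#'
#' @param gt ground-truth values.
#' @param predicted predicted values (same length, `n >= 3`).
#' @param config a [ci_config()].
#' @param units unit label carried into the result.
#' @return list of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`, `ci_loa_upper`,
#'   `units`.
#' @export
bland_altman <- function(gt, predicted, config = ci_config(), units = "") {
  stopifnot(length(gt) == length(predicted))
  n <- length(gt)
  if (n < 3) stop("bland_altman: need at least 3 pairs")
  d <- predicted - gt
  bias <- mean(d)
  s <- stats::sd(d)
  z <- config$z
  tq <- stats::qt((1 + config$confidence_level) / 2, n - 1)
  loa_l <- bias - z * s
  loa_u <- bias + z * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
  structure(list(n = n, bias = bias, sd_diff = s,
                 loa_lower = loa_l, loa_upper = loa_u,
                 ci_bias = c(bias - tq * se_bias, bias + tq * se_bias),
                 ci_loa_lower = c(loa_l - tq * se_loa, loa_l + tq * se_loa),
                 ci_loa_upper = c(loa_u - tq * se_loa, loa_u + tq * se_loa),
                 units = units),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  u <- x$units
  cat(sprintf("<bland_altman> n = %d\n  bias %.3f %s (%.3f to %.3f)\n", x$n,
              x$bias, u, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LoA [%.3f, %.3f] %s; CIs (%.3f to %.3f) / (%.3f to %.3f)\n",
              x$loa_lower, x$loa_upper, u, x$ci_loa_lower[1], x$ci_loa_lower[2],
              x$ci_loa_upper[1], x$ci_loa_upper[2]))
  invisible(x)
}

#' Bland-Altman on matched pairs of a cohort
#'
#' Convenience wrapper extracting ground-truth and predicted sizes from the
#' matched pairs.
#' @inheritParams mae_stratified
#' @return a `bland_altman` result.
#' @export
bland_altman_pairs <- function(match_table, cohort,
                               quantity = c("diameter", "volume"),
                               config = ci_config()) {
  quantity <- match.arg(quantity)
  pr <- .joined_pairs(match_table, cohort)
  col <- if (quantity == "diameter") "avg_diameter_mm" else "volume_mm3"
  bland_altman(pr[[paste0("gt_", col)]], pr[[paste0("cad_", col)]], config,
               units = if (quantity == "diameter") "mm" else "mm3")
}
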