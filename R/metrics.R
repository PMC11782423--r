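#' Scan- and nodule-level detection summary
#'
#' Computes the headline operating-point statistics of a match table:
#' scan-level sensitivity, specificity and precision (Wilson intervals),
#' F1 with a confidence interval, scan-level FPPI (FP scans per
#' nodule-containing scan), nodule-level sensitivity with a Rao-Scott
#' interval clustered by scan, and the FP-finding rate per
#' nodule-containing scan.
#'
#' The F1 score is not a binomial proportion, so its interval is a modeling
#' choice: `f1_method = "clopper_heuristic"` (default) applies
#' Clopper-Pearson to `round(F1 * n)` successes out of
#' `n = TP + (FP + FN)/2` pseudo-trials (F1 is TP over that quantity);
#' `"bootstrap"` resamples scans with replacement and takes percentile
#' bounds. Neither is claimed to match any published F1 interval.
#'
#' @param match_table a [build_match_table()] result.
#' @param config a [ci_config()].
#' @param f1_method `"clopper_heuristic"` or `"bootstrap"`.
#' @param boot_reps bootstrap replicates (bootstrap method only).
#' @param boot_seed seed for the bootstrap.
#' @return list of class `detection_summary`.
#' @export
detection_summary <- function(match_table, config = ci_config(),
                              f1_method = c("clopper_heuristic", "bootstrap"),
                              boot_reps = 2000, boot_seed = 1L) {
  f1_method <- match.arg(f1_method)
  ct <- match_table$counts
  und <- function(num, den) {
    if (den == 0) return(structure(list(undefined = TRUE), class = "undefined_metric"))
    wilson_ci(num, den, config)
  }
  sens <- und(ct$scan_tp, ct$scan_tp + ct$scan_fn)
  spec <- und(ct$scan_tn, ct$scan_tn + ct$scan_fp)
  prec <- und(ct$scan_tp, ct$scan_tp + ct$scan_fp)
  f1 <- if (ct$scan_tp == 0) 0 else {
    p <- ct$scan_tp / (ct$scan_tp + ct$scan_fp)
    r <- ct$scan_tp / (ct$scan_tp + ct$scan_fn)
    2 * p * r / (p + r)
  }
  f1_ci <- NULL
  nh <- ct$scan_tp + (ct$scan_fp + ct$scan_fn) / 2
  if (nh > 0) {
    if (f1_method == "clopper_heuristic") {
      cp <- clopper_pearson_ci(round(f1 * round(nh)), round(nh), config)
      f1_ci <- c(cp$lower, cp$upper)
    } else {
      lab <- match_table$scan_labels$label
      set.seed(boot_seed)
      reps <- vapply(seq_len(boot_reps), function(i) {
        l <- sample(lab, length(lab), replace = TRUE)
        tp <- sum(l == "TP"); fp <- sum(l == "FP"); fn <- sum(l == "FN")
        if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      }, numeric(1))
      alpha <- 1 - config$confidence_level
      f1_ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2)))
    }
  }
  nod_sens <- NULL
  cl <- .nodule_clusters(match_table)
  nod_sens <- if (nrow(cl) >= 2) rao_scott_ci(cl$k, cl$n, config)
              else if (nrow(cl) == 1) wilson_ci(cl$k, cl$n, config)
              else structure(list(undefined = TRUE), class = "undefined_metric")
  structure(list(
    scan_sensitivity = sens, scan_specificity = spec, scan_precision = prec,
    f1 = f1, f1_ci = f1_ci, f1_method = f1_method,
    scan_fppi = if (ct$n_nodule_scans > 0) ct$scan_fp / ct$n_nodule_scans else NA_real_,
    nodule_sensitivity = nod_sens,
    nodule_fp_rate = if (ct$n_nodule_scans > 0)
      ct$fp_in_nodule_scans / ct$n_nodule_scans else NA_real_,
    mean_nodules_per_nodule_scan = if (ct$n_nodule_scans > 0)
      ct$n_gt_nodules / ct$n_nodule_scans else NA_real_,
    mean_iou = match_table$mean_iou, counts = ct),
    class = "detection_summary")
}

# per-scan (cluster) detected/total nodule counts
.nodule_clusters <- function(match_table) {
  tp <- table(match_table$pairs$scan_id)
  fn <- table(match_table$fn_nodules$scan_id)
  sids <- sort(union(names(tp), names(fn)))
  kk <- ifelse(sids %in% names(tp), as.integer(tp[sids]), 0L)
  nn <- kk + ifelse(sids %in% names(fn), as.integer(fn[sids]), 0L)
  data.frame(scan_id = sids, k = kk, n = nn, stringsAsFactors = FALSE)
}

#' @export
print.detection_summary <- function(x, ...) {
  fmt <- function(ci) if (inherits(ci, "proportion_ci")) format(ci) else "undefined"
  cat("<detection_summary>\n")
  cat("  scan sensitivity:  ", fmt(x$scan_sensitivity), "\n")
  cat("  scan specificity:  ", fmt(x$scan_specificity), "\n")
  cat("  scan precision:    ", fmt(x$scan_precision), "\n")
  if (is.null(x$f1_ci)) cat(sprintf("  F1: %.3f\n", x$f1))
  else cat(sprintf("  F1: %.3f (%s: %.3f-%.3f)\n", x$f1, x$f1_method,
                   x$f1_ci[1], x$f1_ci[2]))
  cat(sprintf("  scan FPPI: %.3f; FP findings per nodule scan: %.3f\n",
              x$scan_fppi, x$nodule_fp_rate))
  cat("  nodule sensitivity:", fmt(x$nodule_sensitivity), "\n")
  invisible(x)
}

#' Scan-level ROC and precision-recall analysis
#'
#' Each scan is scored by the maximum finding confidence on it (0 if CAD
#' emitted nothing), with `contains_nodule` as truth. AUC-ROC is the
#' Mann-Whitney statistic with half-credit for ties; its interval uses
#' DeLong's placement-value variance. AUC-PR is stepwise average precision
#' (no interpolation).
#'
#' @param scores numeric per-scan scores.
#' @param truth logical per-scan truth.
#' @param config a [ci_config()].
#' @return list of class `roc_pr`: `roc` and `pr` curve data.frames,
#'   `auc_roc`, `auc_roc_ci`, `auc_roc_se`, `auc_pr`.
#' @export
roc_pr_curves <- function(scores, truth, config = ci_config()) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("roc_pr_curves: both classes must be present")
  x <- scores[truth]; y <- scores[!truth]
  m <- length(x); n <- length(y)
  # DeLong placements
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n, numeric(1))
  v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m, numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - config$z * se), min(1, auc + config$z * se))
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               fpr = sum(y >= t) / n,
               tpr = sum(x >= t) / m)
  }))
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  prr <- do.call(rbind, lapply(thr, function(t) {
    tp <- sum(x >= t); fp <- sum(y >= t)
    data.frame(threshold = t, recall = tp / m,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }))
  rec <- c(0, prr$recall)
  auc_pr <- sum(diff(rec) * prr$precision, na.rm = TRUE)
  structure(list(roc = roc, pr = prr, auc_roc = auc, auc_roc_se = se,
                 auc_roc_ci = ci, auc_pr = auc_pr),
            class = "roc_pr")
}

#' Free-response ROC curve
#'
#' For each distinct confidence threshold (descending), matching is re-run
#' on the findings at or above the threshold; each point reports the
#' nodule-level sensitivity and the average number of unmatched findings
#' (false positives) per scan. Both coordinates are nondecreasing as the
#' threshold falls.
#'
#' @param cohort a `cad_cohort` whose findings carry confidences.
#' @param config a [match_config()].
#' @param denominator_scans `"all"` (default) or `"nodule_containing"`:
#'   which scan count divides the FP tally.
#' @param thresholds optional explicit thresholds (default: all distinct
#'   confidences, descending).
#' @return data.frame of class `froc_curve` with `threshold`,
#'   `avg_fp_per_scan`, `sensitivity`.
#' @export
froc <- function(cohort, config = match_config(),
                 denominator_scans = c("all", "nodule_containing"),
                 thresholds = NULL) {
  denominator_scans <- match.arg(denominator_scans)
  fd <- cohort$findings
  n_gt <- nrow(cohort$nodules)
  contains <- .resolve_contains(cohort$scans, cohort$nodules)
  denom <- if (denominator_scans == "all") nrow(cohort$scans) else sum(contains)
  if (nrow(fd) == 0) {
    out <- data.frame(threshold = Inf, avg_fp_per_scan = 0, sensitivity = 0)
    class(out) <- c("froc_curve", "data.frame")
    return(out)
  }
  if (is.null(thresholds)) thresholds <- sort(unique(fd$confidence), decreasing = TRUE)
  out <- do.call(rbind, lapply(thresholds, function(t) {
    sub <- cohort
    sub$findings <- fd[fd$confidence >= t, , drop = FALSE]
    mt <- build_match_table(sub, config)
    data.frame(threshold = t,
               avg_fp_per_scan = (mt$counts$fp_in_nodule_scans +
                                    mt$counts$fp_in_nonnodule_scans) / denom,
               sensitivity = if (n_gt > 0) mt$counts$nodule_tp / n_gt else NA_real_)
  }))
  class(out) <- c("froc_curve", "data.frame")
  out
}

#' Nodule-level sensitivity by subgroup
#'
#' Partitions ground-truth nodules by a scan-level covariate and reports
#' per-stratum detected/total counts with Rao-Scott intervals (scans as
#' clusters). Strata containing no nodules are omitted with a warning;
#' single-cluster strata fall back to a Wilson interval with a warning.
#'
#' @param match_table a `match_table`.
#' @param cohort the matching `cad_cohort`.
#' @param variable name of a column in `cohort$scans`.
#' @param config a [ci_config()].
#' @return data.frame: `level`, `n_nodules`, `n_detected`, `sensitivity`,
#'   `lower`, `upper`, `method`.
#' @export
subgroup_sensitivity <- function(match_table, cohort, variable,
                                 config = ci_config()) {
  sc <- cohort$scans
  if (!variable %in% names(sc))
    stop("subgroup_sensitivity: unknown scan variable: ", variable)
  cl <- .nodule_clusters(match_table)
  cl$level <- sc[[variable]][match(cl$scan_id, sc$scan_id)]
  levs <- unique(sc[[variable]][sc$scan_id %in% cl$scan_id])
  out <- NULL
  for (lev in levs) {
    sub <- cl[!is.na(cl$level) & cl$level == lev, , drop = FALSE]
    if (nrow(sub) == 0 || sum(sub$n) == 0) {
      warning("subgroup_sensitivity: stratum ", lev, " holds no nodules; omitted")
      next
    }
    ci <- if (nrow(sub) >= 2) rao_scott_ci(sub$k, sub$n, config) else {
      warning("subgroup_sensitivity: stratum ", lev,
              " has a single cluster; Wilson interval used")
      wilson_ci(sum(sub$k), sum(sub$n), config)
    }
    out <- rbind(out, data.frame(level = as.character(lev),
                                 n_nodules = sum(sub$n), n_detected = sum(sub$k),
                                 sensitivity = ci$estimate, lower = ci$lower,
                                 upper = ci$upper, method = ci$method,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Chi-square comparison of covariates between scan groups
#'
#' Pearson chi-square tests (no continuity correction) of each covariate
#' against nodule-containing status, mirroring a descriptive baseline
#' table. Cells with zero expected count raise a flag rather than an error.
#'
#' @param scans scan metadata with resolved `contains_nodule`.
#' @param variables covariate column names.
#' @return named list; per variable: `table`, `statistic`, `df`, `p_value`,
#'   `expected_warning`.
#' @export
compare_covariates <- function(scans,
                               variables = c("age_group", "sex",
                                             "other_abnormality",
                                             "machine_type", "scan_type")) {
  stopifnot("contains_nodule" %in% names(scans))
  grp <- factor(ifelse(scans$contains_nodule, "nodule", "no_nodule"),
                levels = c("nodule", "no_nodule"))
  if (nlevels(droplevels(grp)) < 2)
    stop("compare_covariates: both scan groups must be present")
  out <- list()
  for (v in variables) {
    if (!v %in% names(scans)) stop("compare_covariates: unknown variable: ", v)
    val <- scans[[v]]
    tab <- table(val, grp)
    if (nrow(tab) < 2) stop("compare_covariates: variable ", v, " has < 2 levels")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    flag <- any(expected == 0)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out[[v]] <- list(table = tab, statistic = unname(tst$statistic),
                     df = unname(tst$parameter), p_value = unname(tst$p.value),
                     expected_warning = flag)
  }
  out
}
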