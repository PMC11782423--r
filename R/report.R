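#' Round half-up at a given number of decimals
#'
#' Rendered tables use half-up rounding at the published precision
#' (percentages 1 d.p., F1 3 d.p., mm 2 d.p.); JSON output keeps full
#' precision.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

.pct1 <- function(x) sprintf("%.1f", round_half_up(100 * x, 1))
.ci_str <- function(lower, upper)
  sprintf("(%s–%s)", .pct1(lower), .pct1(upper))

#' Render evaluation results as publication-shaped tables
#'
#' Produces data.frames mirroring the layouts of a validation report:
#' covariate comparison, subgroup sensitivity, detected-vs-missed
#' profile, characterization concordance, and the reader/CAD cross-tab.
#' Percentages are half-up at 1 decimal; intervals render as
#' `"(lower-upper)"`.
#'
#' @param bundle a [run_pipeline()] result (or a list with any of
#'   `covariates`, `subgroups`, `profile`, `concordance`, `cross_tab`).
#' @return named list of data.frames; missing sections are skipped with a
#'   warning.
#' @export
render_tables <- function(bundle) {
  out <- list()
  if (!is.null(bundle$covariates)) {
    rows <- NULL
    for (v in names(bundle$covariates)) {
      cc <- bundle$covariates[[v]]
      tab <- cc$table
      for (r in rownames(tab)) {
        nn <- tab[r, "nodule"]; mm <- tab[r, "no_nodule"]
        rows <- rbind(rows, data.frame(
          variable = v, level = r,
          nodule_scans = sprintf("%d (%s)", nn, .pct1(nn / (nn + mm))),
          no_nodule_scans = sprintf("%d (%s)", mm, .pct1(mm / (nn + mm))),
          p_value = format.pval(cc$p_value, digits = 2, eps = 0.001),
          stringsAsFactors = FALSE))
      }
    }
    out$covariates <- rows
  } else warning("render_tables: covariates section missing; table skipped")
  if (!is.null(bundle$subgroups)) {
    rows <- NULL
    for (v in names(bundle$subgroups)) {
      sg <- bundle$subgroups[[v]]
      rows <- rbind(rows, data.frame(
        variable = v, level = sg$level, n = sg$n_nodules,
        sensitivity = sprintf("%s %s", .pct1(sg$sensitivity),
                              .ci_str(sg$lower, sg$upper)),
        stringsAsFactors = FALSE))
    }
    out$subgroups <- rows
  } else warning("render_tables: subgroup section missing; table skipped")
  if (!is.null(bundle$profile)) {
    pf <- bundle$profile
    out$detected_vs_missed <- data.frame(
      characteristic = pf$characteristic, level = pf$level,
      detected = sprintf("%d (%s)", pf$n_detected, .pct1(pf$pct_detected / 100)),
      missed = sprintf("%d (%s)", pf$n_missed, .pct1(pf$pct_missed / 100)),
      stringsAsFactors = FALSE)
  } else warning("render_tables: detected/missed profile missing; table skipped")
  if (!is.null(bundle$concordance)) {
    rows <- NULL
    for (at in names(bundle$concordance)) {
      ct <- bundle$concordance[[at]]
      pc <- ct$per_class
      rows <- rbind(rows, data.frame(
        attribute = at, gt_class = pc$gt_class, n = pc$n_detected,
        n_correct = pc$n_correct,
        sensitivity = sprintf("%s %s", .pct1(pc$sensitivity),
                              .ci_str(pc$lower, pc$upper)),
        stringsAsFactors = FALSE))
      ov <- ct$overall
      rows <- rbind(rows, data.frame(
        attribute = at, gt_class = "overall", n = ov$denominator,
        n_correct = ov$numerator,
        sensitivity = sprintf("%s %s", .pct1(ov$estimate),
                              .ci_str(ov$lower, ov$upper)),
        stringsAsFactors = FALSE))
    }
    out$concordance <- rows
  } else warning("render_tables: concordance section missing; table skipped")
  if (!is.null(bundle$cross_tab)) {
    xt <- bundle$cross_tab
    out$cross_tab <- rbind(
      data.frame(characteristic = "all", level = "all",
                 n_total = xt$n_nodules,
                 both = unname(xt$counts[["both"]]),
                 only_r1 = unname(xt$counts[["only_r1"]]),
                 only_cad = unname(xt$counts[["only_cad"]]),
                 neither = unname(xt$counts[["neither"]]),
                 stringsAsFactors = FALSE),
      xt$by_characteristic)
  }
  out
}

.ci_json <- function(ci) {
  if (inherits(ci, "proportion_ci"))
    list(numerator = ci$numerator, denominator = ci$denominator,
         estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
         method = ci$method)
  else list(undefined = TRUE)
}

#' Run the full evaluation pipeline
#'
#' read (or accept) a cohort -> match -> evaluate -> characterize ->
#' report. Writes a JSON metrics file, CSV tables, and curve exports to
#' `out_dir`, and returns the bundle invisibly. Pure function of
#' (inputs, config): rerunning with the same inputs reproduces every
#' number.
#'
#' @param cohort a `cad_cohort`, or `NULL` to read from `cohort_dir`.
#' @param cohort_dir directory readable by [read_cohort()].
#' @param out_dir output directory; `NULL` skips file output.
#' @param match a [match_config()].
#' @param ci a [ci_config()].
#' @param subgroup_vars scan covariates for the subgroup table.
#' @param froc_denominator passed to [froc()].
#' @return list of class `cadeval_bundle` with elements `match_table`,
#'   `summary`, `covariates`, `subgroups`, `roc_pr`, `froc`, `profile`,
#'   `concordance`, `mae`, `bland_altman`, `tables`.
#' @export
run_pipeline <- function(cohort = NULL, cohort_dir = NULL, out_dir = NULL,
                         match = match_config(), ci = ci_config(),
                         subgroup_vars = c("age_group", "sex"),
                         froc_denominator = "all") {
  if (is.null(cohort)) {
    if (is.null(cohort_dir)) stop("run_pipeline: provide a cohort or cohort_dir")
    cohort <- read_cohort(cohort_dir)
  }
  cohort$scans$contains_nodule <- .resolve_contains(cohort$scans, cohort$nodules)
  mt <- build_match_table(cohort, match)
  summ <- detection_summary(mt, ci)
  cov <- tryCatch(compare_covariates(cohort$scans), error = function(e) NULL)
  sg <- list()
  for (v in subgroup_vars)
    sg[[v]] <- suppressWarnings(subgroup_sensitivity(mt, cohort, v, ci))
  scores <- vapply(cohort$scans$scan_id, function(s) {
    cf <- cohort$findings$confidence[cohort$findings$scan_id == s]
    if (length(cf)) max(cf) else 0
  }, numeric(1))
  rp <- tryCatch(roc_pr_curves(scores, cohort$scans$contains_nodule, ci),
                 error = function(e) NULL)
  fr <- froc(cohort, match, denominator_scans = froc_denominator)
  prof <- missed_vs_detected_profile(mt, cohort)
  conc <- list()
  for (at in c("texture", "calcification", "spiculation", "lobe"))
    conc[[at]] <- concordance(mt, cohort, at, ci)
  mae <- list(diameter = suppressWarnings(mae_stratified(mt, cohort, "diameter", ci)),
              volume = suppressWarnings(mae_stratified(mt, cohort, "volume", ci)))
  ba <- list(
    diameter = tryCatch(bland_altman_pairs(mt, cohort, "diameter", ci),
                        error = function(e) NULL),
    volume = tryCatch(bland_altman_pairs(mt, cohort, "volume", ci),
                      error = function(e) NULL))
  bundle <- structure(list(match_table = mt, summary = summ, covariates = cov,
                           subgroups = sg, roc_pr = rp, froc = fr,
                           profile = prof, concordance = conc, mae = mae,
                           bland_altman = ba, config = list(match = match, ci = ci)),
                      class = "cadeval_bundle")
  bundle$tables <- suppressWarnings(render_tables(bundle))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    metrics <- list(
      counts = mt$counts, mean_iou = mt$mean_iou,
      match_criterion = match$criterion, iou_threshold = match$iou_threshold,
      scan_sensitivity = .ci_json(summ$scan_sensitivity),
      scan_specificity = .ci_json(summ$scan_specificity),
      scan_precision = .ci_json(summ$scan_precision),
      f1 = summ$f1, f1_ci = summ$f1_ci, f1_method = summ$f1_method,
      scan_fppi = summ$scan_fppi, nodule_fp_rate = summ$nodule_fp_rate,
      nodule_sensitivity = .ci_json(summ$nodule_sensitivity),
      auc_roc = if (!is.null(rp)) rp$auc_roc else NULL,
      auc_roc_ci = if (!is.null(rp)) rp$auc_roc_ci else NULL,
      auc_pr = if (!is.null(rp)) rp$auc_pr else NULL)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (nm in names(bundle$tables))
      .write_csv(bundle$tables[[nm]], file.path(out_dir, paste0("table_", nm, ".csv")))
    if (!is.null(rp)) {
      .write_csv(rp$roc, file.path(out_dir, "curve_roc.csv"))
      .write_csv(rp$pr, file.path(out_dir, "curve_pr.csv"))
    }
    .write_csv(as.data.frame(fr), file.path(out_dir, "curve_froc.csv"))
    write_match_table(mt, out_dir)
  }
  invisible(bundle)
}

#' @export
print.cadeval_bundle <- function(x, ...) {
  cat("<cadeval_bundle>\n")
  print(x$match_table)
  print(x$summary)
  invisible(x)
}
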