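#' Reader annotation sets
#'
#' A reader annotation set is a nodule table in the ground-truth schema
#' (see [cohort]) tagged with a reader id. Report-derived entries may lack
#' masks (`mask` element `NULL`); those pair approximately by lobe and
#' diameter.
#'
#' @param reader_id string.
#' @param nodules nodule table (as in `cad_cohort$nodules`); `mask` entries
#'   may be `NULL` for report-derived records.
#' @return object of class `reader_set`.
#' @export
reader_set <- function(reader_id, nodules = empty_nodule_table()) {
  if (nrow(nodules) && anyDuplicated(paste(nodules$scan_id, nodules$nodule_id)))
    stop("reader_set: duplicate (scan_id, nodule_id) in reader ", reader_id)
  structure(list(reader_id = reader_id, nodules = nodules), class = "reader_set")
}

#' Find discrepancies between the report and the blinded reader
#'
#' Pairs each report-derived nodule with the blinded reader's annotations
#' on the same scan, using the IoU matcher when both carry masks and an
#' approximate rule (same lobe, nearest diameter within 50% relative
#' tolerance) when the report entry has no mask. Paired nodules are
#' concordant (the reader's version is kept); unpaired entries on either
#' side become adjudication records awaiting an arbitrator decision. A
#' scan is discrepant iff it produced at least one record.
#'
#' @param report a [reader_set()] of report-derived nodules.
#' @param r1 a [reader_set()] of the blinded reader's annotations.
#' @param scan_ids all scan ids in scope (concordant scans include those
#'   empty on both sides).
#' @param config a [match_config()].
#' @return list of class `adjudication`: `records` (nodule fields plus
#'   `candidate_id`, `source` in `r1_only`/`report_only`, `approximate`),
#'   `concordant_nodules`, `discrepant_scans`, `concordant_scans`.
#' @export
find_discrepancies <- function(report, r1, scan_ids, config = match_config()) {
  stopifnot(inherits(report, "reader_set"), inherits(r1, "reader_set"))
  rn <- report$nodules; an <- r1$nodules
  records <- NULL
  concordant <- NULL
  for (sid in scan_ids) {
    rs <- rn[rn$scan_id == sid, , drop = FALSE]
    as <- an[an$scan_id == sid, , drop = FALSE]
    paired_r <- logical(nrow(rs)); paired_a <- logical(nrow(as))
    # masked-vs-masked pairing through the IoU matcher
    has_mask_r <- vapply(seq_len(nrow(rs)), function(i) !is.null(rs$mask[[i]]), logical(1))
    if (nrow(rs) && nrow(as) && any(has_mask_r)) {
      fake <- rs[has_mask_r, , drop = FALSE]
      fake$finding_id <- fake$nodule_id
      fake$confidence <- 1
      m <- match_scan(fake, as, config)
      for (k in seq_len(nrow(m$pairs))) {
        ri <- which(rs$nodule_id == m$pairs$finding_id[k] & has_mask_r)[1]
        ai <- which(as$nodule_id == m$pairs$nodule_id[k])[1]
        paired_r[ri] <- TRUE; paired_a[ai] <- TRUE
      }
    }
    # maskless report entries: lobe + nearest diameter within 50%
    for (i in which(!has_mask_r)) {
      cand <- which(!paired_a & as$lobe == rs$lobe[i] &
                      abs(as$avg_diameter_mm - rs$avg_diameter_mm[i]) <=
                        0.5 * rs$avg_diameter_mm[i])
      if (length(cand)) {
        ai <- cand[which.min(abs(as$avg_diameter_mm[cand] - rs$avg_diameter_mm[i]))]
        paired_r[i] <- TRUE; paired_a[ai] <- TRUE
      }
    }
    if (any(paired_a))
      concordant <- rbind(concordant, as[paired_a, , drop = FALSE])
    mk <- function(df, idx, src) {
      if (!length(idx)) return(NULL)
      rec <- df[idx, , drop = FALSE]
      rec$source <- src
      rec$approximate <- if (src == "report_only")
        !vapply(idx, function(i) !is.null(df$mask[[i]]), logical(1)) else FALSE
      rec$candidate_id <- paste(src, rec$scan_id, rec$nodule_id, sep = ":")
      rec
    }
    records <- rbind(records,
                     mk(rs, which(!paired_r), "report_only"),
                     mk(as, which(!paired_a), "r1_only"))
  }
  disc <- if (is.null(records)) character() else unique(records$scan_id)
  if (is.null(concordant)) concordant <- empty_nodule_table()
  if (is.null(records)) {
    records <- empty_nodule_table()
    records$source <- character(); records$approximate <- logical()
    records$candidate_id <- character()
  }
  structure(list(records = records, concordant_nodules = concordant,
                 discrepant_scans = disc,
                 concordant_scans = setdiff(scan_ids, disc)),
            class = "adjudication")
}

#' @export
print.adjudication <- function(x, ...) {
  cat(sprintf("<adjudication> %d records on %d discrepant scans; %d concordant nodules; %d concordant scans\n",
              nrow(x$records), length(x$discrepant_scans),
              nrow(x$concordant_nodules), length(x$concordant_scans)))
  invisible(x)
}

#' Finalize the reference standard
#'
#' Joins the arbitrator's decisions (`accept` keeps a candidate as a true
#' nodule, `reject` discards it) to the adjudication records, appends
#' accepted candidates to the concordant nodules, and recomputes the
#' per-scan `contains_nodule` flags. Every record must be decided.
#' Idempotent: re-running with no new records changes nothing.
#'
#' @param adjudication a [find_discrepancies()] result.
#' @param decisions data.frame with `candidate_id` and `decision`
#'   (`"accept"`/`"reject"`).
#' @param scan_ids all scan ids in scope.
#' @return list: `nodules` (final ground truth), `scan_flags` (data.frame
#'   `scan_id`, `contains_nodule`).
#' @export
finalize_reference <- function(adjudication, decisions, scan_ids) {
  rec <- adjudication$records
  dec <- decisions$decision[match(rec$candidate_id, decisions$candidate_id)]
  if (anyNA(dec))
    stop("finalize_reference: undecided record(s): ",
         paste(utils::head(rec$candidate_id[is.na(dec)], 5), collapse = ", "))
  if (!all(dec %in% c("accept", "reject")))
    stop("finalize_reference: decisions must be 'accept' or 'reject'")
  keep <- rec[dec == "accept", names(empty_nodule_table()), drop = FALSE]
  gt <- rbind(adjudication$concordant_nodules, keep)
  if (nrow(gt)) gt <- gt[order(gt$scan_id, gt$nodule_id), , drop = FALSE]
  rownames(gt) <- NULL
  list(nodules = gt,
       scan_flags = data.frame(scan_id = scan_ids,
                               contains_nodule = scan_ids %in% gt$scan_id,
                               stringsAsFactors = FALSE))
}

# match a reader's annotations against final GT; returns matched GT keys
.reader_matched_keys <- function(cohort, reader, config) {
  nd <- cohort$nodules
  keys <- character()
  fps <- 0L
  for (sid in unique(c(nd$scan_id, reader$nodules$scan_id))) {
    rs <- reader$nodules[reader$nodules$scan_id == sid, , drop = FALSE]
    gs <- nd[nd$scan_id == sid, , drop = FALSE]
    if (nrow(rs) == 0) next
    rs$finding_id <- rs$nodule_id
    rs$confidence <- 1
    m <- match_scan(rs, gs, config)
    keys <- c(keys, paste(sid, m$pairs$nodule_id))
    fps <- fps + length(m$fp_findings)
  }
  list(keys = keys, n_fp = fps)
}

#' Cross-tabulate detections by reader and CAD
#'
#' Labels every ground-truth nodule on the in-scope scans as found by both,
#' only the reader, only CAD, or neither, with a per-characteristic
#' breakdown mirroring the conflicting-scan analysis.
#'
#' @param cohort the finalized `cad_cohort` (ground truth).
#' @param r1 the blinded reader's [reader_set()].
#' @param match_table the CAD `match_table` on the same cohort.
#' @param scope scan ids to tabulate over (default: all scans).
#' @param config a [match_config()] used to match the reader to GT.
#' @return list of class `detection_cross_tab`: `counts` (named vector
#'   both/only_r1/only_cad/neither), `by_characteristic` data.frame,
#'   `n_nodules`.
#' @export
detection_cross_tab <- function(cohort, r1, match_table,
                                scope = cohort$scans$scan_id,
                                config = match_config()) {
  unknown <- setdiff(scope, cohort$scans$scan_id)
  if (length(unknown))
    stop("detection_cross_tab: scope scans absent from cohort: ",
         paste(unknown, collapse = ", "))
  nd <- cohort$nodules[cohort$nodules$scan_id %in% scope, , drop = FALSE]
  rm_ <- .reader_matched_keys(cohort, r1, config)
  key <- paste(nd$scan_id, nd$nodule_id)
  r1_found <- key %in% rm_$keys
  cad_found <- key %in% paste(match_table$pairs$scan_id, match_table$pairs$nodule_id)
  lab <- ifelse(r1_found & cad_found, "both",
         ifelse(r1_found, "only_r1",
         ifelse(cad_found, "only_cad", "neither")))
  lab <- factor(lab, c("both", "only_r1", "only_cad", "neither"))
  feats <- list(
    texture = factor(nd$texture, TEXTURES),
    calcification = factor(ifelse(nd$calcification, "yes", "no"), c("yes", "no")),
    spiculation = factor(ifelse(nd$spiculation, "yes", "no"), c("yes", "no")),
    lobe = factor(nd$lobe, LOBES),
    diameter = .diameter_bins(nd$avg_diameter_mm),
    volume = .volume_bins(nd$volume_mm3))
  byc <- NULL
  for (nm in names(feats)) {
    tb <- table(feats[[nm]], lab)
    byc <- rbind(byc, data.frame(characteristic = nm,
                                 level = rownames(tb),
                                 n_total = as.integer(rowSums(tb)),
                                 both = as.integer(tb[, "both"]),
                                 only_r1 = as.integer(tb[, "only_r1"]),
                                 only_cad = as.integer(tb[, "only_cad"]),
                                 neither = as.integer(tb[, "neither"]),
                                 stringsAsFactors = FALSE))
  }
  structure(list(counts = table(lab), n_nodules = nrow(nd),
                 by_characteristic = byc),
            class = "detection_cross_tab")
}

#' @export
print.detection_cross_tab <- function(x, ...) {
  cat(sprintf("<detection_cross_tab> %d nodules: both %d / only_r1 %d / only_cad %d / neither %d\n",
              x$n_nodules, x$counts[["both"]], x$counts[["only_r1"]],
              x$counts[["only_cad"]], x$counts[["neither"]]))
  invisible(x)
}

#' Reader versus CAD performance and second-reader uplift
#'
#' Reader sensitivity is the fraction of ground-truth nodules the reader
#' annotated (IoU-matched); CAD sensitivity comes from the match table.
#' The uplift is the number of nodules found only by CAD divided by the
#' number found by the reader: the minimum relative gain the reader would
#' obtain by accepting every extra CAD detection.
#'
#' @param cohort the finalized `cad_cohort`.
#' @param r1 the reader's [reader_set()].
#' @param match_table CAD `match_table` on the same cohort.
#' @param config_ci a [ci_config()].
#' @param config_match a [match_config()].
#' @return list of class `reader_performance`: `r1_sensitivity`
#'   (`proportion_ci`), `cad_sensitivity`, `uplift` (list with numerator,
#'   denominator, fraction), `r1_fp_count`.
#' @export
reader_performance <- function(cohort, r1, match_table,
                               config_ci = ci_config(),
                               config_match = match_config()) {
  nd <- cohort$nodules
  n_gt <- nrow(nd)
  rm_ <- .reader_matched_keys(cohort, r1, config_match)
  key <- paste(nd$scan_id, nd$nodule_id)
  r1_found <- key %in% rm_$keys
  cad_found <- key %in% paste(match_table$pairs$scan_id, match_table$pairs$nodule_id)
  r1_sens <- if (n_gt > 0) wilson_ci(sum(r1_found), n_gt, config_ci)
             else structure(list(undefined = TRUE), class = "undefined_metric")
  cad_sens <- if (n_gt > 0) wilson_ci(sum(cad_found), n_gt, config_ci)
              else structure(list(undefined = TRUE), class = "undefined_metric")
  upl_num <- sum(cad_found & !r1_found)
  upl_den <- sum(r1_found)
  structure(list(r1_sensitivity = r1_sens, cad_sensitivity = cad_sens,
                 uplift = list(numerator = upl_num, denominator = upl_den,
                               fraction = if (upl_den > 0) upl_num / upl_den else NA_real_),
                 r1_fp_count = rm_$n_fp),
            class = "reader_performance")
}

#' @export
print.reader_performance <- function(x, ...) {
  cat("<reader_performance>\n  R1: ", format(x$r1_sensitivity),
      "\n  CAD:", format(x$cad_sensitivity), "\n")
  cat(sprintf("  uplift: %d/%d = %.1f%%; R1 false positives: %d\n",
              x$uplift$numerator, x$uplift$denominator,
              100 * x$uplift$fraction, x$r1_fp_count))
  invisible(x)
}
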