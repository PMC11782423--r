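#' Matching configuration
#'
#' The study scores CAD findings against ground truth with a 10% 3D-overlap
#' rule. Two readings of that rule are supported: `"iou"` (default;
#' intersection over union of the two masks >= threshold) and
#' `"overlap_over_finding"` (intersection over the finding's own volume
#' >= threshold, the literal "at least 10% of its volume" reading).
#'
#' @param iou_threshold overlap threshold in `(0, 1]`, default 0.10.
#' @param criterion `"iou"` or `"overlap_over_finding"`.
#' @return object of class `match_config`.
#' @export
match_config <- function(iou_threshold = 0.10,
                         criterion = c("iou", "overlap_over_finding")) {
  stopifnot(is.numeric(iou_threshold), iou_threshold > 0, iou_threshold <= 1)
  criterion <- match.arg(criterion)
  structure(list(iou_threshold = iou_threshold, criterion = criterion),
            class = "match_config")
}

#' Match one scan's findings to its ground-truth nodules
#'
#' Builds the exact one-to-one assignment that maximizes first the number
#' of matched pairs and then the total overlap score, over all candidate
#' (finding, nodule) pairs meeting the threshold. A dynamic program over
#' nodule subsets makes this exact and fast: the cohort's own rule of at
#' most 10 nodules per scan bounds the state space at 2^10. Among equal
#' optima, candidates are tried in descending score (ties: higher finding
#' confidence, then lexicographic ids), which reproduces the familiar
#' greedy pairing whenever greedy is optimal and resolves the rest
#' deterministically. Remaining findings are false positives, remaining
#' nodules false negatives.
#'
#' @param findings finding table rows for one scan (may be empty).
#' @param nodules ground-truth rows for the same scan (may be empty).
#' @param config a [match_config()].
#' @return list with `pairs` (finding_id, nodule_id, iou, score),
#'   `fp_findings`, `fn_nodules` (character vectors of ids).
#' @export
match_scan <- function(findings, nodules, config = match_config()) {
  nf <- nrow(findings); nn <- nrow(nodules)
  pairs <- data.frame(finding_id = character(), nodule_id = character(),
                      iou = numeric(), score = numeric(), stringsAsFactors = FALSE)
  if (nf > 0 && nn > 0) {
    if (nn > 16)
      stop("match_scan: more than 16 nodules on one scan (cohort cap is 10)")
    iou_m <- matrix(0, nf, nn); score_m <- matrix(0, nf, nn)
    for (i in seq_len(nf)) {
      for (j in seq_len(nn)) {
        iou_m[i, j] <- iou3d(findings$mask[[i]], nodules$mask[[j]])
        score_m[i, j] <- if (config$criterion == "iou") iou_m[i, j] else
          overlap_fraction(findings$mask[[i]], nodules$mask[[j]])
      }
    }
    # deterministic finding order: descending best score, conf, then id
    ford <- order(-apply(score_m, 1, max), -findings$confidence,
                  findings$finding_id)
    sel <- .optimal_assignment(score_m, ford, config$iou_threshold,
                               nodules$nodule_id)
    if (nrow(sel)) {
      sel <- sel[order(-sel$score, findings$finding_id[sel$i]), , drop = FALSE]
      pairs <- data.frame(finding_id = findings$finding_id[sel$i],
                          nodule_id = nodules$nodule_id[sel$j],
                          iou = iou_m[cbind(sel$i, sel$j)],
                          score = sel$score, stringsAsFactors = FALSE)
    }
  }
  list(pairs = pairs,
       fp_findings = setdiff(findings$finding_id, pairs$finding_id),
       fn_nodules = setdiff(nodules$nodule_id, pairs$nodule_id))
}

# exact max-cardinality, max-total-score one-to-one assignment via DP over
# nodule bitmasks; findings processed in the given order, candidates in
# descending score; first-found optimum kept (deterministic)
.optimal_assignment <- function(score_m, ford, thr, nodule_ids) {
  nf <- nrow(score_m); nn <- ncol(score_m)
  ns <- bitwShiftL(1L, nn)
  card <- rep(-1L, ns); tot <- rep(-Inf, ns)
  card[1] <- 0L; tot[1] <- 0
  choice <- vector("list", nf)
  for (fi in seq_len(nf)) {
    f <- ford[fi]
    cand <- which(score_m[f, ] >= thr)
    if (length(cand) > 1)
      cand <- cand[order(-score_m[f, cand], nodule_ids[cand])]
    ch <- integer(ns); pv <- seq_len(ns) - 1L   # default: skip this finding
    if (length(cand)) {
      nc <- card; nt <- tot
      for (s in which(card >= 0L) - 1L) {
        for (j in cand) {
          bit <- bitwShiftL(1L, j - 1L)
          if (bitwAnd(s, bit) == 0L) {
            s2 <- bitwOr(s, bit)
            c2 <- card[s + 1L] + 1L
            t2 <- tot[s + 1L] + score_m[f, j]
            if (c2 > nc[s2 + 1L] ||
                (c2 == nc[s2 + 1L] && t2 > nt[s2 + 1L] + 1e-12)) {
              nc[s2 + 1L] <- c2; nt[s2 + 1L] <- t2
              ch[s2 + 1L] <- j; pv[s2 + 1L] <- s
            }
          }
        }
      }
      card <- nc; tot <- nt
    }
    choice[[fi]] <- list(ch = ch, pv = pv)
  }
  ok <- which(card >= 0L)
  best <- ok[order(-card[ok], -tot[ok], ok)][1]
  s <- best - 1L
  out <- NULL
  for (fi in rev(seq_len(nf))) {
    j <- choice[[fi]]$ch[s + 1L]
    if (j > 0L) {
      out <- rbind(out, data.frame(i = ford[fi], j = j,
                                   score = score_m[ford[fi], j]))
      s <- choice[[fi]]$pv[s + 1L]
    }
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(), score = numeric())
  else out
}

#' Scan-level TP/FN/FP/TN labels
#'
#' A nodule-containing scan is TP if at least one finding matched a nodule
#' there, else FN. A non-nodule-containing scan is FP if CAD emitted any
#' finding on it, else TN.
#'
#' @param scan_results named list of [match_scan()] results, one per scan,
#'   names are scan ids. Scans with no entry count as having no findings.
#' @param scans scan metadata with resolved `contains_nodule`.
#' @param n_findings named integer vector: findings emitted per scan
#'   (defaults to what `scan_results` implies).
#' @return named character vector of labels `TP`/`FN`/`FP`/`TN`.
#' @export
classify_scans <- function(scan_results, scans, n_findings = NULL) {
  if (is.null(n_findings))
    n_findings <- vapply(scan_results, function(r)
      nrow(r$pairs) + length(r$fp_findings), integer(1))
  lab <- character(nrow(scans)); names(lab) <- scans$scan_id
  for (i in seq_len(nrow(scans))) {
    sid <- scans$scan_id[i]
    res <- scan_results[[sid]]
    npair <- if (is.null(res)) 0L else nrow(res$pairs)
    nfind <- if (sid %in% names(n_findings)) n_findings[[sid]] else 0L
    has_gt <- isTRUE(scans$contains_nodule[i])
    if (!has_gt && !is.null(res) && npair + length(res$fn_nodules) > 0)
      stop("classify_scans: scan ", sid,
           " has GT nodules but contains_nodule is not TRUE", call. = FALSE)
    lab[i] <- if (has_gt) {
      if (npair > 0) "TP" else "FN"
    } else {
      if (nfind > 0) "FP" else "TN"
    }
  }
  lab
}

#' Match a whole cohort and tabulate the outcome
#'
#' Runs [match_scan()] per scan and [classify_scans()] across the cohort.
#'
#' @param cohort a `cad_cohort`.
#' @param config a [match_config()].
#' @return object of class `match_table`: `pairs` (with scan_id),
#'   `fn_nodules`, `fp_findings` (data.frames with scan_id and an
#'   `in_nodule_scan` flag), `scan_labels` (data.frame scan_id/label),
#'   `counts` (nodule- and scan-level tallies) and `mean_iou` of matched
#'   pairs.
#' @export
build_match_table <- function(cohort, config = match_config()) {
  sc <- cohort$scans; nd <- cohort$nodules; fd <- cohort$findings
  results <- list()
  pairs <- NULL; fns <- NULL; fps <- NULL
  for (sid in sc$scan_id) {
    f <- fd[fd$scan_id == sid, , drop = FALSE]
    n <- nd[nd$scan_id == sid, , drop = FALSE]
    if (nrow(f) == 0 && nrow(n) == 0) next
    r <- match_scan(f, n, config)
    results[[sid]] <- r
    if (nrow(r$pairs)) pairs <- rbind(pairs, cbind(scan_id = sid, r$pairs))
    if (length(r$fn_nodules))
      fns <- rbind(fns, data.frame(scan_id = sid, nodule_id = r$fn_nodules,
                                   stringsAsFactors = FALSE))
    if (length(r$fp_findings))
      fps <- rbind(fps, data.frame(scan_id = sid, finding_id = r$fp_findings,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(pairs))
    pairs <- data.frame(scan_id = character(), finding_id = character(),
                        nodule_id = character(), iou = numeric(),
                        score = numeric(), stringsAsFactors = FALSE)
  if (is.null(fns))
    fns <- data.frame(scan_id = character(), nodule_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(fps))
    fps <- data.frame(scan_id = character(), finding_id = character(),
                      stringsAsFactors = FALSE)
  contains <- .resolve_contains(sc, nd)
  sc$contains_nodule <- contains
  labels <- classify_scans(results, sc)
  fps$in_nodule_scan <- contains[match(fps$scan_id, sc$scan_id)]
  counts <- list(
    nodule_tp = nrow(pairs), nodule_fn = nrow(fns),
    fp_in_nodule_scans = sum(fps$in_nodule_scan),
    fp_in_nonnodule_scans = sum(!fps$in_nodule_scan),
    scan_tp = sum(labels == "TP"), scan_fn = sum(labels == "FN"),
    scan_fp = sum(labels == "FP"), scan_tn = sum(labels == "TN"),
    n_nodule_scans = sum(contains), n_nonnodule_scans = sum(!contains),
    n_gt_nodules = nrow(nd))
  structure(list(pairs = pairs, fn_nodules = fns, fp_findings = fps,
                 scan_labels = data.frame(scan_id = sc$scan_id, label = unname(labels),
                                          stringsAsFactors = FALSE),
                 counts = counts,
                 mean_iou = if (nrow(pairs)) mean(pairs$iou) else NA_real_,
                 config = config),
            class = "match_table")
}

# contains_nodule from metadata when set, else inferred from GT presence;
# error if metadata contradicts the GT table.
.resolve_contains <- function(scans, nodules) {
  inferred <- scans$scan_id %in% nodules$scan_id
  stated <- scans$contains_nodule
  bad <- !is.na(stated) & !stated & inferred
  if (any(bad))
    stop("cohort: scan(s) ", paste(scans$scan_id[bad], collapse = ", "),
         " carry GT nodules but contains_nodule = FALSE", call. = FALSE)
  ifelse(is.na(stated), inferred, stated | inferred)
}

#' @export
print.match_table <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("<match_table> nodule level: %d TP / %d FN; FPs: %d in nodule scans, %d in non-nodule scans\n",
              ct$nodule_tp, ct$nodule_fn, ct$fp_in_nodule_scans, ct$fp_in_nonnodule_scans))
  cat(sprintf("  scan level: %d TP / %d FN / %d FP / %d TN; mean matched IoU %.3f\n",
              ct$scan_tp, ct$scan_fn, ct$scan_fp, ct$scan_tn, x$mean_iou))
  invisible(x)
}

#' Serialize a match table
#'
#' Writes `pairs.csv`, `fn_nodules.csv`, `fp_findings.csv` and a JSON count
#' summary.
#' @param match_table a `match_table`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_match_table <- function(match_table, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(pairs = file.path(out_dir, "pairs.csv"),
             fn = file.path(out_dir, "fn_nodules.csv"),
             fp = file.path(out_dir, "fp_findings.csv"),
             labels = file.path(out_dir, "scan_labels.csv"),
             summary = file.path(out_dir, "match_summary.json"))
  .write_csv(match_table$pairs, paths["pairs"])
  .write_csv(match_table$fn_nodules, paths["fn"])
  .write_csv(match_table$fp_findings, paths["fp"])
  .write_csv(match_table$scan_labels, paths["labels"])
  jsonlite::write_json(c(match_table$counts, list(mean_iou = match_table$mean_iou)),
                       paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
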