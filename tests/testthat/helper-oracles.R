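# Independent oracles used by the property and acceptance tests. These are
# deliberately naive (enumeration / closed form / tail bisection) and share
# no code with the implementation paths they check.

# exhaustive best one-to-one assignment: maximize cardinality, then total score
oracle_assignment <- function(score, thr) {
  nf <- nrow(score); nn <- ncol(score)
  best <- list(card = -1L, tot = -Inf)
  rec <- function(i, used, card, tot) {
    if (i > nf) {
      if (card > best$card || (card == best$card && tot > best$tot + 1e-12))
        best <<- list(card = card, tot = tot)
      return(invisible())
    }
    rec(i + 1L, used, card, tot)
    for (j in seq_len(nn)) {
      if (!used[j] && score[i, j] >= thr)
        rec(i + 1L, `[<-`(used, j, TRUE), card + 1L, tot + score[i, j])
    }
  }
  rec(1L, logical(nn), 0L, 0)
  best
}

# AUC as the literal pairwise Mann-Whitney count with half credit for ties
oracle_auc <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  tot <- 0
  for (xi in x) for (yi in y)
    tot <- tot + if (xi > yi) 1 else if (xi == yi) 0.5 else 0
  tot / (length(x) * length(y))
}

# Clopper-Pearson bounds by bisection on binomial tail probabilities
oracle_clopper <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else
    bisect(function(p) sum(stats::dbinom(k:n, n, p)) <= alpha / 2, 0, k / n)
  upper <- if (k == n) 1 else
    bisect(function(p) sum(stats::dbinom(0:k, n, p)) > alpha / 2, k / n, 1)
  c(lower, upper)
}

# ratio-estimator variance for clustered binary data, written out long-hand
oracle_ratio_var <- function(k, n) {
  m <- length(k)
  p <- sum(k) / sum(n)
  resid2 <- (k - p * n)^2
  m / (m - 1) * sum(resid2) / sum(n)^2
}

# random geometric matching instance: ellipsoid nodules plus findings that
# are jittered copies of nodules (75%) or unrelated blobs (25%) - the way
# CAD findings arise
random_match_instance <- function(seed, max_side = 6L) {
  set.seed(seed)
  g <- c(40L, 40L, 40L)
  nn <- sample(seq_len(max_side), 1)
  nf <- sample(seq_len(max_side), 1)
  nod <- lapply(seq_len(nn), function(j)
    rasterize_ellipsoid(stats::runif(3, 8, 32), rep(stats::runif(1, 2, 5), 3), g))
  fnd <- lapply(seq_len(nf), function(i) {
    if (stats::runif(1) < 0.75) {
      m <- nod[[sample(nn, 1)]]
      tryCatch(cadeval:::shift_mask(m, round(stats::runif(3, -4, 4))),
               error = function(e) m)
    } else {
      rasterize_ellipsoid(stats::runif(3, 8, 32), rep(stats::runif(1, 2, 4), 3), g)
    }
  })
  ndf <- data.frame(nodule_id = sprintf("N%02d", seq_len(nn)))
  ndf$mask <- I(nod)
  fdf <- data.frame(finding_id = sprintf("F%02d", seq_len(nf)),
                    confidence = round(stats::runif(nf), 3))
  fdf$mask <- I(fnd)
  score <- matrix(0, nf, nn)
  for (i in seq_len(nf)) for (j in seq_len(nn))
    score[i, j] <- iou3d(fnd[[i]], nod[[j]])
  list(findings = fdf, nodules = ndf, score = score)
}

# tiny hand-assembled cohort: 3 scans, 2 nodules, findings as requested
toy_cohort <- function(with_findings = TRUE) {
  g <- c(24L, 24L, 24L)
  m1 <- rasterize_ellipsoid(c(6.5, 6.5, 12.5), c(2.5, 2.5, 2.5), g)
  m2 <- rasterize_ellipsoid(c(17.5, 6.5, 12.5), c(3, 3, 4), g)
  scans <- data.frame(scan_id = c("A", "B", "C"),
                      contains_nodule = c(TRUE, TRUE, FALSE),
                      age_group = c("under_55", "55_plus", "55_plus"),
                      sex = c("male", "female", "male"),
                      other_abnormality = c(TRUE, FALSE, FALSE),
                      machine_type = "M1",
                      scan_type = c("contrast", "noncontrast", "contrast"),
                      slice_thickness_mm = 1, stringsAsFactors = FALSE)
  mk_meas <- function(m) measure_nodule(m)
  nodules <- data.frame(scan_id = c("A", "B"), nodule_id = c("N1", "N1"),
                        texture = c("solid", "ground_glass"),
                        calcification = c(FALSE, TRUE),
                        spiculation = c(FALSE, FALSE),
                        lobe = c("right_upper", "left_lower"),
                        avg_diameter_mm = c(mk_meas(m1)$avg_diameter_mm,
                                            mk_meas(m2)$avg_diameter_mm),
                        volume_mm3 = c(mk_meas(m1)$volume_mm3,
                                       mk_meas(m2)$volume_mm3),
                        stringsAsFactors = FALSE)
  nodules$mask <- I(list(m1, m2))
  findings <- if (with_findings) {
    f1 <- m1                                         # exact hit on A:N1
    f2 <- rasterize_ellipsoid(c(6.5, 17.5, 12.5), c(2, 2, 2), g)  # FP on C
    fd <- data.frame(scan_id = c("A", "C"), finding_id = c("F1", "F1"),
                     confidence = c(0.9, 0.3),
                     texture = c("solid", "solid"),
                     calcification = FALSE, spiculation = FALSE,
                     lobe = c("right_upper", "middle"),
                     avg_diameter_mm = c(mk_meas(f1)$avg_diameter_mm,
                                         mk_meas(f2)$avg_diameter_mm),
                     volume_mm3 = c(mk_meas(f1)$volume_mm3,
                                    mk_meas(f2)$volume_mm3),
                     stringsAsFactors = FALSE)
    fd$mask <- I(list(f1, f2))
    fd
  } else empty_finding_table()
  new_cohort(scans, nodules, findings)
}
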