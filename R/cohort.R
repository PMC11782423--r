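#' Cohort data model
#'
#' A cohort bundles three tables:
#' \describe{
#'   \item{scans}{one row per CT scan: `scan_id`, `contains_nodule`,
#'     `age_group` (`under_55`/`55_plus`), `sex`, `other_abnormality`,
#'     `machine_type`, `scan_type` (`contrast`/`noncontrast`),
#'     `slice_thickness_mm`.}
#'   \item{nodules}{ground-truth annotations: `scan_id`, `nodule_id`,
#'     `texture` (`solid`/`part_solid`/`ground_glass`), `calcification`,
#'     `spiculation`, `lobe`, `avg_diameter_mm`, `volume_mm3`, and a `mask`
#'     list-column of [voxel_mask()] objects.}
#'   \item{findings}{CAD output with the same characteristic columns plus
#'     `finding_id` and `confidence` in `[0, 1]`.}
#' }
#'
#' @name cohort
NULL

TEXTURES <- c("solid", "part_solid", "ground_glass")
LOBES    <- c("right_upper", "middle", "right_lower", "left_upper", "left_lower")

#' Empty annotation / finding tables with the right schema
#' @return zero-row data.frame.
#' @export
empty_nodule_table <- function() {
  data.frame(scan_id = character(), nodule_id = character(),
             texture = character(), calcification = logical(),
             spiculation = logical(), lobe = character(),
             avg_diameter_mm = numeric(), volume_mm3 = numeric(),
             mask = I(list()), stringsAsFactors = FALSE)
}

#' @rdname empty_nodule_table
#' @export
empty_finding_table <- function() {
  data.frame(scan_id = character(), finding_id = character(),
             confidence = numeric(), texture = character(),
             calcification = logical(), spiculation = logical(),
             lobe = character(), avg_diameter_mm = numeric(),
             volume_mm3 = numeric(), mask = I(list()),
             stringsAsFactors = FALSE)
}

#' Construct and validate a cohort
#'
#' @param scans scan metadata data.frame (see [cohort]). Missing covariate
#'   columns are filled with `NA`; `slice_thickness_mm` defaults to 1.
#' @param nodules ground-truth nodule table; defaults to empty.
#' @param findings CAD finding table; defaults to empty.
#' @param validate run [validate_cohort()]?
#' @param strict escalate range violations to errors (see
#'   [validate_cohort()]).
#' @return object of class `cad_cohort`.
#' @export
new_cohort <- function(scans, nodules = empty_nodule_table(),
                       findings = empty_finding_table(),
                       validate = TRUE, strict = TRUE) {
  stopifnot(is.data.frame(scans), "scan_id" %in% names(scans))
  scans$scan_id <- as.character(scans$scan_id)
  for (col in c("age_group", "sex", "machine_type", "scan_type"))
    if (is.null(scans[[col]])) scans[[col]] <- NA_character_
  for (col in c("contains_nodule", "other_abnormality"))
    if (is.null(scans[[col]])) scans[[col]] <- NA
  if (is.null(scans$slice_thickness_mm)) scans$slice_thickness_mm <- 1
  x <- structure(list(scans = scans, nodules = nodules, findings = findings),
                 class = "cad_cohort")
  if (validate) validate_cohort(x, strict = strict)
  x
}

#' @export
print.cad_cohort <- function(x, ...) {
  cat(sprintf("<cad_cohort> %d scans (%d nodule-containing), %d GT nodules, %d CAD findings\n",
              nrow(x$scans), sum(x$scans$contains_nodule, na.rm = TRUE),
              nrow(x$nodules), nrow(x$findings)))
  invisible(x)
}

.check <- function(ok, msg, strict, what = "error") {
  if (ok) return(invisible(TRUE))
  if (strict && what == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  invisible(FALSE)
}

#' Validate cohort invariants
#'
#' Checks referential integrity (every nodule/finding `scan_id` exists),
#' uniqueness of identifiers, the 3-30 mm nodule definition, consistency of
#' the recorded volume with the mask volume (1% tolerance), the <= 10
#' nodules per scan and <= 5 mm slice-thickness exclusion rules, confidence
#' range, and that all masks of a scan share one grid. With
#' `strict = FALSE` range violations (diameter, volume consistency, slice
#' thickness) downgrade to warnings; structural violations always error.
#'
#' @param cohort a `cad_cohort`.
#' @param strict logical.
#' @return `TRUE` invisibly (or an error/warnings).
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  sc <- cohort$scans; nd <- cohort$nodules; fd <- cohort$findings
  if (anyDuplicated(sc$scan_id))
    stop("validate_cohort: duplicate scan_id: ",
         paste(unique(sc$scan_id[duplicated(sc$scan_id)]), collapse = ", "), call. = FALSE)
  .check(all(is.na(sc$slice_thickness_mm) | sc$slice_thickness_mm <= 5),
         "validate_cohort: slice_thickness_mm > 5 mm violates the inclusion rule",
         strict)
  orph <- setdiff(unique(c(nd$scan_id, fd$scan_id)), sc$scan_id)
  if (length(orph))
    stop("validate_cohort: nodules/findings reference unknown scan_id: ",
         paste(orph, collapse = ", "), call. = FALSE)
  if (nrow(nd)) {
    key <- paste(nd$scan_id, nd$nodule_id)
    if (anyDuplicated(key))
      stop("validate_cohort: duplicate (scan_id, nodule_id): ",
           paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
    percnt <- table(nd$scan_id)
    if (any(percnt > 10))
      stop("validate_cohort: > 10 nodules on scan(s) ",
           paste(names(percnt)[percnt > 10], collapse = ", "),
           " (study exclusion rule)", call. = FALSE)
    bad <- which(!(nd$avg_diameter_mm > 3 & nd$avg_diameter_mm < 30))
    .check(length(bad) == 0,
           paste0("validate_cohort: avg_diameter_mm outside (3, 30) mm for nodule(s) ",
                  paste(paste(nd$scan_id[bad], nd$nodule_id[bad], sep = ":"),
                        collapse = ", ")), strict)
    if (!all(nd$texture %in% TEXTURES)) stop("validate_cohort: invalid texture value")
    if (!all(nd$lobe %in% LOBES)) stop("validate_cohort: invalid lobe value")
    for (i in seq_len(nrow(nd))) {
      mv <- mask_volume(nd$mask[[i]])
      .check(abs(nd$volume_mm3[i] - mv) <= 0.01 * mv,
             sprintf("validate_cohort: recorded volume %.1f differs from mask volume %.1f by > 1%% (%s:%s)",
                     nd$volume_mm3[i], mv, nd$scan_id[i], nd$nodule_id[i]), strict)
    }
  }
  if (nrow(fd)) {
    key <- paste(fd$scan_id, fd$finding_id)
    if (anyDuplicated(key))
      stop("validate_cohort: duplicate (scan_id, finding_id)", call. = FALSE)
    if (any(fd$confidence < 0 | fd$confidence > 1))
      stop("validate_cohort: confidence outside [0, 1]", call. = FALSE)
  }
  # one grid per scan across GT and CAD masks
  allm <- c(stats::setNames(nd$mask, nd$scan_id), stats::setNames(fd$mask, fd$scan_id))
  if (length(allm)) {
    by_scan <- split(allm, names(allm))
    for (sid in names(by_scan)) {
      ms <- by_scan[[sid]]
      if (length(ms) > 1 && !all(vapply(ms[-1], .same_grid, logical(1), b = ms[[1]])))
        stop("validate_cohort: masks of scan ", sid, " are not on one grid", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

.mask_rows <- function(masks, role, scan_ids, object_ids) {
  if (length(masks) == 0)
    return(data.frame(role = character(), scan_id = character(),
                      object_id = character(), x = integer(), y = integer(),
                      z = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(masks), function(i) {
    v <- masks[[i]]$voxels
    data.frame(role = role, scan_id = scan_ids[i], object_id = object_ids[i],
               x = v[, 1], y = v[, 2], z = v[, 3], stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `scans.csv`, `nodules.csv`, `findings.csv`, `masks.csv` (one row
#' per voxel, keyed by role/scan/object), `grids.csv` (per-scan grid shape
#' and spacing) and a `manifest.json`. The representation round-trips
#' bit-identically through [read_cohort()].
#'
#' @param cohort a validated `cad_cohort`.
#' @param out_dir directory (created if absent).
#' @return invisibly, the manifest as a named list.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("write_cohort: cannot create directory ", out_dir)
  nd <- cohort$nodules; fd <- cohort$findings
  .write_csv(cohort$scans, file.path(out_dir, "scans.csv"))
  .write_csv(nd[setdiff(names(nd), "mask")], file.path(out_dir, "nodules.csv"))
  .write_csv(fd[setdiff(names(fd), "mask")], file.path(out_dir, "findings.csv"))
  masks <- rbind(.mask_rows(nd$mask, "gt", nd$scan_id, nd$nodule_id),
                 .mask_rows(fd$mask, "finding", fd$scan_id, fd$finding_id))
  .write_csv(masks, file.path(out_dir, "masks.csv"))
  allm <- c(nd$mask, fd$mask)
  sids <- c(nd$scan_id, fd$scan_id)
  grids <- unique(do.call(rbind, lapply(seq_along(allm), function(i) {
    m <- allm[[i]]
    data.frame(scan_id = sids[i],
               nx = m$grid_shape[1], ny = m$grid_shape[2], nz = m$grid_shape[3],
               sx = m$spacing_mm[1], sy = m$spacing_mm[2], sz = m$spacing_mm[3],
               stringsAsFactors = FALSE)
  })))
  if (is.null(grids))
    grids <- data.frame(scan_id = character(), nx = integer(), ny = integer(),
                        nz = integer(), sx = numeric(), sy = numeric(),
                        sz = numeric(), stringsAsFactors = FALSE)
  .write_csv(grids, file.path(out_dir, "grids.csv"))
  manifest <- list(format = "cadeval-cohort", version = 1L,
                   files = list(scans = "scans.csv", nodules = "nodules.csv",
                                findings = "findings.csv", masks = "masks.csv",
                                grids = "grids.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.read_csv <- function(path, classes = NA) {
  if (!file.exists(path)) stop("read_cohort: missing file ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
}

.attach_masks <- function(df, id_col, role, masks, grids) {
  if (nrow(df) == 0) { df$mask <- I(list()); return(df) }
  sub <- masks[masks$role == role, , drop = FALSE]
  df$mask <- I(lapply(seq_len(nrow(df)), function(i) {
    sid <- df$scan_id[i]; oid <- df[[id_col]][i]
    g <- grids[grids$scan_id == sid, , drop = FALSE]
    if (nrow(g) == 0)
      stop("read_cohort: no grid recorded for scan ", sid, call. = FALSE)
    v <- sub[sub$scan_id == sid & sub$object_id == oid, c("x", "y", "z"), drop = FALSE]
    if (nrow(v) == 0)
      stop("read_cohort: no mask voxels for ", role, " ", sid, ":", oid, call. = FALSE)
    voxel_mask(as.matrix(v), c(g$nx[1], g$ny[1], g$nz[1]), c(g$sx[1], g$sy[1], g$sz[1]))
  }))
  df
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @param validate,strict see [validate_cohort()].
#' @return a `cad_cohort`.
#' @export
read_cohort <- function(dir, validate = TRUE, strict = TRUE) {
  if (!dir.exists(dir)) stop("read_cohort: no such directory: ", dir, call. = FALSE)
  scans <- .read_csv(file.path(dir, "scans.csv"))
  scans$scan_id <- as.character(scans$scan_id)
  nodules <- .read_csv(file.path(dir, "nodules.csv"))
  findings <- .read_csv(file.path(dir, "findings.csv"))
  masks <- .read_csv(file.path(dir, "masks.csv"))
  grids <- .read_csv(file.path(dir, "grids.csv"))
  if (nrow(nodules)) {
    nodules$scan_id <- as.character(nodules$scan_id)
    nodules$nodule_id <- as.character(nodules$nodule_id)
  } else nodules <- empty_nodule_table()[setdiff(names(empty_nodule_table()), "mask")]
  if (nrow(findings)) {
    findings$scan_id <- as.character(findings$scan_id)
    findings$finding_id <- as.character(findings$finding_id)
  } else findings <- empty_finding_table()[setdiff(names(empty_finding_table()), "mask")]
  if (nrow(masks)) {
    masks$scan_id <- as.character(masks$scan_id)
    masks$object_id <- as.character(masks$object_id)
  }
  grids$scan_id <- as.character(grids$scan_id)
  nodules <- .attach_masks(nodules, "nodule_id", "gt", masks, grids)
  findings <- .attach_masks(findings, "finding_id", "finding", masks, grids)
  new_cohort(scans, nodules, findings, validate = validate, strict = strict)
}
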