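#' Voxel masks
#'
#' A `voxel_mask` is the 3D substrate on which findings and ground-truth
#' nodules are compared: a set of occupied voxels on a regular grid with
#' known physical spacing. Voxel indices are 0-based triples `(x, y, z)`
#' with `z` the slice (axial) axis; the physical center of voxel
#' `(i, j, k)` is `((i + 0.5) * sx, (j + 0.5) * sy, (k + 0.5) * sz)` mm.
#' All masks belonging to one scan must share a single grid.
#'
#' @param voxels integer matrix with 3 columns (or coercible), 0-based
#'   voxel indices; duplicates are removed and rows are stored in a
#'   canonical (linear-index) order so identical sets compare identical.
#' @param grid_shape integer triple, grid dimensions.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, grid_shape, spacing_mm = c(1, 1, 1)) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3L, byrow = TRUE)
  voxels <- matrix(as.integer(round(voxels)), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0), all(grid_shape > 0L))
  if (nrow(voxels) == 0L) stop("voxel_mask: mask must contain at least one voxel")
  if (any(voxels < 0L) || any(voxels >= matrix(grid_shape, nrow(voxels), 3L, byrow = TRUE)))
    stop("voxel_mask: voxel indices out of grid bounds")
  key <- .vox_key(voxels, grid_shape)
  keep <- !duplicated(key)
  voxels <- voxels[keep, , drop = FALSE]
  voxels <- voxels[order(key[keep]), , drop = FALSE]
  structure(list(voxels = voxels, grid_shape = grid_shape, spacing_mm = spacing_mm),
            class = "voxel_mask")
}

# linear voxel index (double arithmetic; exact below 2^53)
.vox_key <- function(v, shape) {
  v[, 1] + as.numeric(shape[1]) * (v[, 2] + as.numeric(shape[2]) * v[, 3])
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels on %s grid, spacing %s mm, volume %.1f mm^3\n",
              nrow(x$voxels), paste(x$grid_shape, collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"), mask_volume(x)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a `voxel_mask`.
#' @return integer count.
#' @export
mask_size <- function(mask) nrow(mask$voxels)

#' Physical volume of a mask in cubic millimetres
#'
#' Exactly `voxel count * prod(spacing)`.
#' @param mask a `voxel_mask`.
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) nrow(mask$voxels) * prod(mask$spacing_mm)

.same_grid <- function(a, b) {
  identical(a$grid_shape, b$grid_shape) &&
    isTRUE(all(abs(a$spacing_mm - b$spacing_mm) < 1e-9))
}

#' 3D intersection-over-union of two masks
#'
#' The Jaccard overlap `|A n B| / |A u B|` of the two voxel sets. This is
#' the quantity thresholded (at 0.10 by default) when deciding whether a
#' CAD finding hits a ground-truth nodule.
#'
#' @param a,b `voxel_mask` objects on the same grid.
#' @return a number in `[0, 1]`; 1 iff identical sets, 0 iff disjoint.
#' @export
iou3d <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!.same_grid(a, b)) stop("iou3d: masks are on different grids")
  ka <- .vox_key(a$voxels, a$grid_shape)
  kb <- .vox_key(b$voxels, b$grid_shape)
  inter <- sum(ka %in% kb)
  inter / (length(ka) + length(kb) - inter)
}

#' Overlap fraction of a finding with a nodule
#'
#' `|A n B| / |A|`: the fraction of mask `a`'s volume covered by `b`.
#' This is the literal reading of "at least 10% of its volume had overlap",
#' available as the alternate matching criterion.
#' @param a,b `voxel_mask` objects on the same grid.
#' @return a number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (!.same_grid(a, b)) stop("overlap_fraction: masks are on different grids")
  ka <- .vox_key(a$voxels, a$grid_shape)
  kb <- .vox_key(b$voxels, b$grid_shape)
  sum(ka %in% kb) / length(ka)
}

#' Rasterize an ellipsoid onto a voxel grid
#'
#' A voxel is included iff its center lies inside (or on) the ellipsoid.
#' Deterministic; used both to build synthetic nodules and as the documented
#' exchange format for mask-free annotations.
#'
#' @param center_mm physical center (mm), numeric triple.
#' @param semi_axes_mm positive semi-axis lengths (mm), numeric triple,
#'   aligned with the grid axes.
#' @param grid_shape integer triple.
#' @param voxel_spacing_mm positive numeric triple.
#' @return a `voxel_mask`.
#' @export
rasterize_ellipsoid <- function(center_mm, semi_axes_mm, grid_shape,
                                voxel_spacing_mm = c(1, 1, 1)) {
  stopifnot(all(semi_axes_mm > 0))
  grid_shape <- as.integer(grid_shape)
  sp <- as.numeric(voxel_spacing_mm)
  lo <- pmax(0L, as.integer(floor((center_mm - semi_axes_mm) / sp - 0.5)))
  hi <- pmin(grid_shape - 1L, as.integer(ceiling((center_mm + semi_axes_mm) / sp - 0.5)))
  if (any(lo > hi)) stop("rasterize_ellipsoid: ellipsoid lies outside the grid")
  idx <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  ctr <- sweep(sweep(idx + 0.5, 2, sp, `*`), 2, center_mm, `-`)
  inside <- rowSums(sweep(ctr, 2, semi_axes_mm, `/`)^2) <= 1
  if (!any(inside)) stop("rasterize_ellipsoid: no voxel center falls inside the ellipsoid")
  voxel_mask(idx[inside, , drop = FALSE], grid_shape, sp)
}

#' Measure a nodule mask
#'
#' Volume is exactly voxel count times voxel volume. The average diameter
#' follows the clinical convention of averaging the long and short axes,
#' operationalized here on the axial slice of largest in-plane area: the
#' long axis is the maximum Feret diameter of the slice (max center-to-center
#' distance plus half an in-plane voxel as boundary correction; a
#' single-voxel slice has extent one voxel), and the short axis is the
#' maximal extent perpendicular to the long-axis direction on that slice.
#' Ties in slice area break to the lowest slice index; ties in the Feret
#' pair to the first pair found.
#'
#' @param mask a nonempty `voxel_mask`.
#' @return list with `avg_diameter_mm` and `volume_mm3`.
#' @export
measure_nodule <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  v <- mask$voxels
  if (nrow(v) == 0L) stop("measure_nodule: empty mask")
  sp <- mask$spacing_mm
  vol <- nrow(v) * prod(sp)
  area_by_z <- table(v[, 3])
  z0 <- as.integer(names(area_by_z)[which.max(area_by_z)])
  sl <- v[v[, 3] == z0, 1:2, drop = FALSE]
  xy <- cbind((sl[, 1] + 0.5) * sp[1], (sl[, 2] + 0.5) * sp[2])
  ip <- mean(sp[1:2])  # half an in-plane voxel corrects center-distance extents
  if (nrow(xy) == 1L) {
    long <- ip
    short <- ip
  } else {
    h <- if (nrow(xy) > 3L) {
      hull <- grDevices::chull(xy)
      xy[hull, , drop = FALSE]
    } else xy
    d2 <- as.matrix(stats::dist(h))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    long <- max(d2) + ip / 2
    u <- h[ij[2], ] - h[ij[1], ]
    u <- u / sqrt(sum(u^2))
    perp <- c(-u[2], u[1])
    proj <- xy %*% perp
    short <- diff(range(proj)) + ip / 2
  }
  list(avg_diameter_mm = (long + short) / 2, volume_mm3 = vol)
}

# Translate a mask by an integer voxel offset, dropping voxels that leave
# the grid. Errors if nothing remains.
shift_mask <- function(mask, delta) {
  v <- sweep(mask$voxels, 2, as.integer(round(delta)), `+`)
  ok <- rowSums(v < 0L) == 0 &
    rowSums(v >= matrix(mask$grid_shape, nrow(v), 3, byrow = TRUE)) == 0
  if (!any(ok)) stop("shift_mask: translated mask falls entirely off the grid")
  voxel_mask(v[ok, , drop = FALSE], mask$grid_shape, mask$spacing_mm)
}
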