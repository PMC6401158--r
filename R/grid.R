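#' Voxel grid geometry
#'
#' A `voxel_grid` describes the common sampling lattice shared by every mask
#' and dose array of one patient. The axis convention is fixed throughout the
#' package: axis 1 = x, increasing right-to-left of the patient; axis 2 = y,
#' increasing anterior-to-posterior; axis 3 = z, increasing inferior-to-
#' superior. Voxel centers sit at `origin_mm + (index - 1) * spacing_mm`
#' (1-based array indices), and all geometric operators classify voxels by
#' their center point.
#'
#' @param dims integer vector of length 3, array dimensions (all >= 1).
#' @param spacing_mm numeric vector of length 3, voxel spacing in mm (> 0).
#' @param origin_mm numeric vector of length 3, physical coordinate of the
#'   center of voxel (1,1,1), in mm. Defaults to c(0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing_mm, origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(dims) == 3L, length(spacing_mm) == 3L, length(origin_mm) == 3L)
  if (any(dims < 1L)) stop("grid dims must be positive")
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("grid spacing must be strictly positive")
  structure(list(dims = dims, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "objects") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch: %s are not on the same voxel grid", what))
  invisible(TRUE)
}

#' Physical coordinates of voxel centers along one axis
#' @param grid a `voxel_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of length `dims[axis]`, mm.
#' @export
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing_mm[axis]
}

#' Volume of one voxel in cubic centimetres
#' @param grid a `voxel_grid`.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing_mm) / 1000

#' Binary region-of-interest mask
#'
#' @param roi_name name of the region of interest.
#' @param grid the `voxel_grid` the mask lives on.
#' @param voxels logical (or 0/1) 3-D array matching `grid$dims`.
#' @param allow_empty permit an all-FALSE mask (derived subvolumes may be
#'   empty on degenerate geometry; organ masks may not).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(roi_name, grid, voxels, allow_empty = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.numeric(voxels)) {
    bad <- !(voxels %in% c(0, 1))
    if (any(bad)) stop(sprintf("mask '%s' is not binary", roi_name))
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  stopifnot(is.logical(voxels))
  if (!all(dim(voxels) == grid$dims))
    stop(sprintf("mask '%s' dims do not match its grid", roi_name))
  if (!allow_empty && !any(voxels))
    stop(sprintf("mask '%s' is empty", roi_name))
  structure(list(roi_name = roi_name, grid = grid, voxels = voxels),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels (%.2f cc)\n", x$roi_name,
              sum(x$voxels), mask_volume_cc(x)))
  invisible(x)
}

#' Mask volume in cc (voxel count times voxel volume, exactly)
#' @param mask a `roi_mask`.
#' @export
mask_volume_cc <- function(mask) sum(mask$voxels) * voxel_volume_cc(mask$grid)

#' Physical centroid of a mask (mean of voxel-center coordinates), mm
#' @param mask a `roi_mask`.
#' @return numeric length-3 vector (x, y, z) in mm.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop(sprintf("mask '%s' is empty", mask$roi_name))
  g <- mask$grid
  c(mean(g$origin_mm[1] + (idx[, 1] - 1) * g$spacing_mm[1]),
    mean(g$origin_mm[2] + (idx[, 2] - 1) * g$spacing_mm[2]),
    mean(g$origin_mm[3] + (idx[, 3] - 1) * g$spacing_mm[3]))
}

# mm coordinates (n x 3) of all TRUE voxel centers
mask_coords_mm <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  g <- mask$grid
  cbind(g$origin_mm[1] + (idx[, 1] - 1) * g$spacing_mm[1],
        g$origin_mm[2] + (idx[, 2] - 1) * g$spacing_mm[2],
        g$origin_mm[3] + (idx[, 3] - 1) * g$spacing_mm[3])
}

# derive a new mask on the same grid from a logical array
mask_like <- function(mask, voxels, roi_name = mask$roi_name) {
  roi_mask(roi_name, mask$grid, voxels, allow_empty = TRUE)
}

#' Dose grid in centigray
#'
#' @param grid a `voxel_grid`.
#' @param values numeric 3-D array of absorbed dose in cGy; finite, >= 0.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!all(dim(values) == grid$dims)) stop("dose dims do not match grid")
  nonfin <- which(!is.finite(values))
  if (length(nonfin) > 0L) {
    ijk <- arrayInd(nonfin[1], grid$dims)
    stop(sprintf("dose contains a non-finite value at voxel (%d, %d, %d)",
                 ijk[1], ijk[2], ijk[3]))
  }
  if (any(values < 0)) stop("dose must be nonnegative everywhere")
  structure(list(grid = grid, values = values), class = "dose_grid")
}

#' Co-registered organ masks plus tumor laterality
#'
#' Bundles the five organ-at-risk masks the pipeline consumes — left and right
#' parotid (PG), left and right submandibular gland (SMG), and mandible — on a
#' single voxel grid, together with the primary-tumor laterality that defines
#' the ipsilateral/contralateral frame.
#'
#' @param PG_left,PG_right,SMG_left,SMG_right,mandible `roi_mask` objects on a
#'   common grid.
#' @param tumor_laterality `"left"` or `"right"`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(PG_left, PG_right, SMG_left, SMG_right, mandible,
                          tumor_laterality) {
  masks <- list(PG_left = PG_left, PG_right = PG_right,
                SMG_left = SMG_left, SMG_right = SMG_right,
                mandible = mandible)
  for (m in masks) stopifnot(inherits(m, "roi_mask"))
  g <- PG_left$grid
  for (nm in names(masks)) stop_if_grid_mismatch(g, masks[[nm]]$grid, nm)
  if (length(tumor_laterality) != 1L || !tumor_laterality %in% c("left", "right"))
    stop("tumor_laterality must be 'left' or 'right'")
  structure(c(masks, list(tumor_laterality = tumor_laterality, grid = g)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set (tumor %s):\n", x$tumor_laterality))
  for (nm in c("PG_left", "PG_right", "SMG_left", "SMG_right", "mandible"))
    cat(sprintf("  %-10s %6d voxels (%.1f cc)\n", nm, sum(x[[nm]]$voxels),
                mask_volume_cc(x[[nm]])))
  invisible(x)
}
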