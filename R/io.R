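#' Read a NIfTI volume as a mask or dose grid
#'
#' Parses grid metadata (dims, spacing, origin) from the NIfTI header,
#' validates the voxel payload, and returns the package container. Masks must
#' be strictly 0/1; doses must be finite and nonnegative (a NaN voxel is
#' reported with its index). If a session grid is supplied, agreement is
#' enforced at load.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param what `"mask"`, `"dose"`, or `"auto"` (mask iff all values are 0/1).
#' @param roi_name name for a loaded mask (defaults to the file stem).
#' @param grid optional `voxel_grid` the volume must match.
#' @return A `roi_mask` or `dose_grid`.
#' @export
load_volume <- function(path, what = c("auto", "mask", "dose"),
                        roi_name = NULL, grid = NULL) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  if (length(dim(vals)) != 3L) stop("expected a 3-D volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  g <- voxel_grid(dim(vals), sp, origin)
  if (!is.null(grid)) stop_if_grid_mismatch(grid, g, basename(path))
  if (is.null(roi_name)) roi_name <- sub("\\.nii(\\.gz)?$", "", basename(path))

  is_binary <- all(vals %in% c(0, 1))
  if (what == "auto") what <- if (is_binary) "mask" else "dose"
  if (what == "mask") {
    if (!is_binary)
      stop(sprintf("mask file '%s' is non-binary (contains values other than 0/1)",
                   basename(path)))
    roi_mask(roi_name, g, vals != 0, allow_empty = TRUE)
  } else {
    nonfin <- which(!is.finite(vals))
    if (length(nonfin) > 0L) {
      ijk <- arrayInd(nonfin[1], dim(vals))
      stop(sprintf("dose file '%s' has a non-finite value at voxel (%d, %d, %d)",
                   basename(path), ijk[1], ijk[2], ijk[3]))
    }
    dose_grid(g, vals)
  }
}

#' Write a mask or dose grid as NIfTI
#'
#' Grid spacing and origin are stored in the header (qform), so
#' `write_volume` then [load_volume()] is the identity on values and grid
#' metadata.
#'
#' @param x a `roi_mask` or `dose_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    vals <- array(as.integer(x$voxels), dim = x$grid$dims)
    g <- x$grid
    dt <- "uint8"
  } else if (inherits(x, "dose_grid")) {
    vals <- x$values
    g <- x$grid
    dt <- "float"
  } else stop("x must be a roi_mask or dose_grid")
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- g$spacing_mm
  xf <- diag(c(g$spacing_mm, 1))
  xf[1:3, 4] <- g$origin_mm
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write a table as CSV with a units header line
#'
#' Every numeric output file of the pipeline carries a leading comment line
#' naming the units of its columns (cGy, cc, days, ...).
#'
#' @param df data.frame.
#' @param path output CSV path.
#' @param units one-line units description.
#' @export
write_table_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_units()]
#' @param path CSV path.
#' @export
read_table_units <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}
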