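#' Map paired organs to ipsilateral / contralateral roles
#'
#' Assigns each parotid and submandibular gland an ipsilateral or
#' contralateral role from the primary-tumor laterality. Organs on the tumor
#' side become ipsilateral; the mandible carries no role.
#'
#' @param structures a `structure_set`.
#' @return A list with elements `iPG`, `cPG`, `iSMG`, `cSMG` (the role-named
#'   `roi_mask`s), `i_side` / `c_side` (`"left"` / `"right"`), and `roles`, a
#'   named character vector mapping organ name to role.
#' @export
map_laterality <- function(structures) {
  stopifnot(inherits(structures, "structure_set"))
  side <- structures$tumor_laterality
  if (is.null(side) || !side %in% c("left", "right"))
    stop("tumor laterality missing or invalid; cannot map ipsilateral/contralateral")
  other <- if (side == "left") "right" else "left"
  list(
    iPG  = structures[[paste0("PG_", side)]],
    cPG  = structures[[paste0("PG_", other)]],
    iSMG = structures[[paste0("SMG_", side)]],
    cSMG = structures[[paste0("SMG_", other)]],
    i_side = side, c_side = other,
    roles = c(
      stats::setNames("ipsilateral",  paste0("PG_", side)),
      stats::setNames("contralateral", paste0("PG_", other)),
      stats::setNames("ipsilateral",  paste0("SMG_", side)),
      stats::setNames("contralateral", paste0("SMG_", other))
    )
  )
}

#' Expand a binary mask by an isotropic physical margin
#'
#' Returns every voxel whose center lies within `margin_mm` (Euclidean
#' distance, honoring anisotropic voxel spacing) of some voxel center of the
#' input mask, including the input mask itself — the "contour + shell" used
#' for the salivary glands. Implemented as binary dilation with the
#' spacing-aware ellipsoidal structuring element, i.e. thresholding the
#' Euclidean distance transform of the mask at `margin_mm`.
#'
#' @param mask a nonempty `roi_mask`.
#' @param margin_mm nonnegative margin in mm (the pipeline default is 3).
#' @return The expanded `roi_mask` (superset of the input).
#' @export
expand_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!is.finite(margin_mm) || margin_mm < 0) stop("margin_mm must be >= 0")
  if (!any(mask$voxels)) stop(sprintf("cannot expand empty mask '%s'", mask$roi_name))
  if (margin_mm == 0) return(mask)
  sp <- mask$grid$spacing_mm
  r <- floor(margin_mm / sp + 1e-9)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (off$dx * sp[1])^2 + (off$dy * sp[2])^2 + (off$dz * sp[3])^2
  off <- off[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  dm <- mask$grid$dims
  # dilate inside a bounding box padded by the kernel radius, then paste back
  idx <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - r, 1L)
  hi <- pmin(apply(idx, 2, max) + r, dm)
  sub <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dms <- dim(sub)
  acc <- sub
  for (k in seq_len(nrow(off))) {
    sh <- shift_array(sub, c(off$dx[k], off$dy[k], off$dz[k]), dms)
    acc <- acc | sh
  }
  out <- mask$voxels
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- acc
  mask_like(mask, out)
}

# which indices along `axis` contain at least one TRUE voxel
axis_presence <- function(arr, axis) {
  d <- dim(arr)
  if (axis == 1L) {
    rowSums(matrix(arr, nrow = d[1])) > 0
  } else {
    cs <- matrix(colSums(matrix(arr, nrow = d[1])), nrow = d[2])
    if (axis == 2L) rowSums(cs) > 0 else colSums(cs) > 0
  }
}

# shift a logical array by integer voxel offsets, padding with FALSE
shift_array <- function(a, off, dm) {
  if (all(off == 0)) return(a)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { src[[ax]] <- seq_len(dm[ax] - o); dst[[ax]] <- (1 + o):dm[ax] }
    else        { src[[ax]] <- (1 - o):dm[ax];      dst[[ax]] <- seq_len(dm[ax] + o) }
    if (length(src[[ax]]) == 0L) return(array(FALSE, dim = dm))
  }
  out <- array(FALSE, dim = dm)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Split a mask into superior / middle / inferior thirds
#'
#' Cuts the physical z-extent of the mask's voxel centers at one third and two
#' thirds of the span. Voxels are classified by center z; a center exactly on
#' a cut plane goes to the more inferior section. A mask confined to a single
#' z-slice is returned entirely in the middle section with a warning.
#'
#' @param mask a nonempty `roi_mask`.
#' @return Named list of three `roi_mask`s: `sup`, `mid`, `inf` — an exact
#'   partition of the input.
#' @export
split_si_thirds <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot split empty mask")
  g <- mask$grid
  z <- g$origin_mm[3] + (idx[, 3] - 1) * g$spacing_mm[3]
  zmin <- min(z); zmax <- max(z)
  empty <- array(FALSE, dim = g$dims)
  if (zmax == zmin) {
    warning(sprintf("mask '%s' spans a single z-slice; assigning all voxels to the middle section",
                    mask$roi_name))
    return(list(sup = mask_like(mask, empty, paste0(mask$roi_name, "_sup")),
                mid = mask_like(mask, mask$voxels, paste0(mask$roi_name, "_mid")),
                inf = mask_like(mask, empty, paste0(mask$roi_name, "_inf"))))
  }
  c1 <- zmin + (zmax - zmin) / 3
  c2 <- zmin + 2 * (zmax - zmin) / 3
  lab <- c("inf", "mid", "sup")[1L + (z > c1) + (z > c2)]
  out <- list()
  for (s in c("sup", "mid", "inf")) {
    v <- empty
    v[idx[lab == s, , drop = FALSE]] <- TRUE
    out[[s]] <- mask_like(mask, v, paste0(mask$roi_name, "_", s))
  }
  out
}

#' Split a gland into medial / anterior / posterior radial sectors
#'
#' Partitions the mask into three 120-degree wedges in the axial plane about
#' the whole-gland 3-D centroid projected onto that plane. The medial sector
#' is centered on the in-plane unit vector pointing toward the patient
#' midline (-x for a left-side gland, +x for a right-side gland); the
#' anterior sector is centered on the medial vector rotated 120 degrees
#' toward anterior (-y); the posterior sector is the remainder. One angular
#' frame is used for the whole gland. Voxels whose angle falls exactly on a
#' wedge boundary go to the first sector in the cyclic order medial ->
#' anterior -> posterior at that boundary.
#'
#' @param mask a nonempty `roi_mask` (one gland).
#' @param side patient side of the gland, `"left"` or `"right"`; defines the
#'   medial direction.
#' @return Named list of three `roi_mask`s: `med`, `ant`, `post` — an exact
#'   partition of the input.
#' @export
split_radial_sectors <- function(mask, side) {
  stopifnot(inherits(mask, "roi_mask"), side %in% c("left", "right"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot split empty mask")
  if (nrow(idx) == 1L)
    warning(sprintf("mask '%s' is degenerate (single voxel); assigning to medial sector",
                    mask$roi_name))
  g <- mask$grid
  cen <- mask_centroid(mask)
  x <- g$origin_mm[1] + (idx[, 1] - 1) * g$spacing_mm[1]
  y <- g$origin_mm[2] + (idx[, 2] - 1) * g$spacing_mm[2]
  # in-plane basis: m = medial unit vector, a = anterior (-y)
  mx <- if (side == "left") -1 else 1
  u <- (x - cen[1]) * mx          # component along medial
  v <- -(y - cen[2])              # component along anterior
  theta <- atan2(v, u) * 180 / pi # in (-180, 180]; medial sector centered at 0
  lab <- ifelse(theta > -60 & theta <= 60, "med",
                ifelse(theta > 60, "ant", "post"))
  empty <- array(FALSE, dim = g$dims)
  out <- list()
  for (s in c("med", "ant", "post")) {
    vox <- empty
    vox[idx[lab == s, , drop = FALSE]] <- TRUE
    out[[s]] <- mask_like(mask, vox, paste0(mask$roi_name, "_", s))
  }
  out
}

#' Partition an expanded parotid into its nine named sectors
#'
#' Composes the superior/middle/inferior thirds with the medial/anterior/
#' posterior radial split. The radial split is computed once on the whole
#' gland (a single angular frame shared by all three SI sections) and then
#' intersected with each SI section.
#'
#' @param pg_expanded the expanded parotid `roi_mask`.
#' @param side patient side of the gland, `"left"` or `"right"`.
#' @return Named list of nine `roi_mask`s, names `(sup|mid|inf)_(med|ant|post)`,
#'   an exact partition of the input.
#' @export
partition_parotid <- function(pg_expanded, side) {
  thirds <- split_si_thirds(pg_expanded)
  sectors <- split_radial_sectors(pg_expanded, side)
  out <- list()
  for (si in c("sup", "mid", "inf")) {
    for (rs in c("med", "ant", "post")) {
      nm <- paste0(si, "_", rs)
      out[[nm]] <- mask_like(pg_expanded,
                             thirds[[si]]$voxels & sectors[[rs]]$voxels,
                             paste0(pg_expanded$roi_name, "_", nm))
    }
  }
  out
}

#' Build the ipsilateral / contralateral oral-cavity surrogate
#'
#' The oral cavity is frequently not contoured, so a geometric surrogate is
#' used: the grid region outside the (expanded) parotids, (expanded)
#' submandibular glands and mandible, bounded superiorly by the lower two
#' thirds of the parotids, inferiorly by the inferior-most submandibular
#' extent, anteriorly/posteriorly by the mandible's extents, and laterally by
#' the lateral extents of the two expanded parotids. The region is split into
#' halves at the midsagittal plane halfway between the two parotid centroids,
#' the ipsilateral half on the tumor side.
#'
#' @param pg_i,pg_c expanded ipsilateral / contralateral parotid `roi_mask`s.
#' @param smg_i,smg_c expanded submandibular `roi_mask`s.
#' @param mandible mandible `roi_mask`.
#' @param i_side tumor side, `"left"` or `"right"`.
#' @return List with `iOC` and `cOC` `roi_mask`s.
#' @export
build_oc_surrogate <- function(pg_i, pg_c, smg_i, smg_c, mandible, i_side) {
  stopifnot(i_side %in% c("left", "right"))
  g <- pg_i$grid
  for (m in list(pg_c, smg_i, smg_c, mandible))
    stop_if_grid_mismatch(g, m$grid, "oral-cavity inputs")
  pg_union <- pg_i$voxels | pg_c$voxels
  smg_union <- smg_i$voxels | smg_c$voxels
  zc <- axis_coords(g, 3); yc <- axis_coords(g, 2); xc <- axis_coords(g, 1)

  pg_z <- range(zc[axis_presence(pg_union, 3)])
  z_sup_bound <- pg_z[1] + 2 / 3 * (pg_z[2] - pg_z[1])  # top of lower 2/3 of PGs
  z_inf_bound <- min(zc[axis_presence(smg_union, 3)])
  y_rng <- range(yc[axis_presence(mandible$voxels, 2)])
  x_rng <- range(xc[axis_presence(pg_union, 1)])

  in_x <- xc >= x_rng[1] & xc <= x_rng[2]
  in_y <- yc >= y_rng[1] & yc <= y_rng[2]
  in_z <- zc >= z_inf_bound & zc <= z_sup_bound
  if (!any(in_z)) {
    which_bound <- if (z_sup_bound < z_inf_bound)
      "superior PG-lower-2/3 bound lies below the inferior SMG bound" else "z band empty"
    stop(sprintf("oral-cavity surrogate collapsed: %s", which_bound))
  }
  cand <- array(FALSE, dim = g$dims)
  cand[in_x, in_y, in_z] <- TRUE
  cand <- cand & !(pg_union | smg_union | mandible$voxels)
  if (!any(cand))
    stop("oral-cavity surrogate collapsed: all candidate voxels belong to PG/SMG/mandible")

  x_mid <- (mask_centroid(pg_i)[1] + mask_centroid(pg_c)[1]) / 2
  left_cols <- xc >= x_mid   # +x is patient left; plane ties go to the left half
  left_half <- cand; left_half[!left_cols, , ] <- FALSE
  right_half <- cand; right_half[left_cols, , ] <- FALSE
  if (i_side == "left") {
    list(iOC = roi_mask("iOC", g, left_half, allow_empty = TRUE),
         cOC = roi_mask("cOC", g, right_half, allow_empty = TRUE))
  } else {
    list(iOC = roi_mask("iOC", g, right_half, allow_empty = TRUE),
         cOC = roi_mask("cOC", g, left_half, allow_empty = TRUE))
  }
}

#' Derive the 22 named subvolumes from a structure set
#'
#' Runs the full geometric pipeline: laterality mapping, 3 mm expansion of
#' parotids and submandibular glands, the 3x3 parotid partition (superior/
#' middle/inferior by medial/anterior/posterior), and the oral-cavity
#' surrogate split into ipsilateral/contralateral halves — 18 parotid sectors
#' + 2 SMG + 2 OC = 22 subvolumes.
#'
#' @param structures a `structure_set`.
#' @param margin_mm expansion margin in mm, default 3.
#' @return An object of class `subvolume_set`: a named list of 22 `roi_mask`s
#'   (names `iOC`, `cOC`, `iSMG`, `cSMG`, and `(i|c)PG_(sup|mid|inf)_(med|ant|post)`)
#'   with the grid and margin attached.
#' @export
derive_subvolumes <- function(structures, margin_mm = 3) {
  roles <- map_laterality(structures)
  pg_i <- expand_mask(roles$iPG, margin_mm); pg_i$roi_name <- "iPG"
  pg_c <- expand_mask(roles$cPG, margin_mm); pg_c$roi_name <- "cPG"
  smg_i <- expand_mask(roles$iSMG, margin_mm); smg_i$roi_name <- "iSMG"
  smg_c <- expand_mask(roles$cSMG, margin_mm); smg_c$roi_name <- "cSMG"

  sec_i <- partition_parotid(pg_i, roles$i_side)
  sec_c <- partition_parotid(pg_c, roles$c_side)
  oc <- build_oc_surrogate(pg_i, pg_c, smg_i, smg_c, structures$mandible,
                           roles$i_side)

  masks <- list(iOC = oc$iOC, cOC = oc$cOC, iSMG = smg_i, cSMG = smg_c)
  for (nm in names(sec_i)) masks[[paste0("iPG_", nm)]] <- sec_i[[nm]]
  for (nm in names(sec_c)) masks[[paste0("cPG_", nm)]] <- sec_c[[nm]]
  for (nm in names(masks)) masks[[nm]]$roi_name <- nm
  stopifnot(length(masks) == 22L)
  structure(list(masks = masks, grid = structures$grid, margin_mm = margin_mm,
                 expanded = list(iPG = pg_i, cPG = pg_c, iSMG = smg_i, cSMG = smg_c)),
            class = "subvolume_set")
}

#' @export
print.subvolume_set <- function(x, ...) {
  cat(sprintf("subvolume_set: %d subvolumes (margin %.1f mm)\n",
              length(x$masks), x$margin_mm))
  invisible(x)
}

#' Subvolume names in canonical (lexical) order
#' @return Character vector of the 22 subvolume names, sorted.
#' @export
subvolume_names <- function() {
  pg <- as.vector(outer(c("iPG", "cPG"), outer(c("sup", "mid", "inf"),
        c("med", "ant", "post"), paste, sep = "_"), paste, sep = "_"))
  sort(c("iOC", "cOC", "iSMG", "cSMG", pg))
}
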