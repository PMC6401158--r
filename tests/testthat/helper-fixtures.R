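# geometry fixtures built in code

tiny_grid <- function(dims = c(12, 12, 12), spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_grid(dims, spacing, origin)
}

# axis-aligned box mask over inclusive index ranges
box_mask <- function(grid, xr, yr, zr, name = "box") {
  v <- array(FALSE, dim = grid$dims)
  v[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  roi_mask(name, grid, v)
}

# digital sphere: voxels whose center is within radius_mm of center_mm
sphere_mask <- function(grid, center_mm, radius_mm, name = "sphere") {
  qx <- (axis_coords(grid, 1) - center_mm[1])^2
  qy <- (axis_coords(grid, 2) - center_mm[2])^2
  qz <- (axis_coords(grid, 3) - center_mm[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  roi_mask(name, grid, q <= radius_mm^2)
}

# solid cylinder along z
cylinder_mask <- function(grid, center_xy, radius_mm, zr, name = "cyl") {
  dx2 <- (axis_coords(grid, 1) - center_xy[1])^2
  dy2 <- (axis_coords(grid, 2) - center_xy[2])^2
  disc <- outer(dx2, dy2, "+") <= radius_mm^2
  v <- array(FALSE, dim = grid$dims)
  for (k in zr[1]:zr[2]) v[, , k] <- disc
  roi_mask(name, grid, v)
}

# reflect a mask across the grid midsagittal plane (x axis reversal)
mirror_mask <- function(mask) {
  roi_mask(mask$roi_name, mask$grid, mask$voxels[rev(seq_len(mask$grid$dims[1])), , ],
           allow_empty = TRUE)
}

# reflect a whole structure set and flip tumor laterality
mirror_structures <- function(ss) {
  structure_set(
    PG_left = mirror_mask(ss$PG_right), PG_right = mirror_mask(ss$PG_left),
    SMG_left = mirror_mask(ss$SMG_right), SMG_right = mirror_mask(ss$SMG_left),
    mandible = mirror_mask(ss$mandible),
    tumor_laterality = if (ss$tumor_laterality == "left") "right" else "left"
  )
}

# config with anatomy jitter switched off (deterministic mirror geometry)
rigid_config <- function(n = 1, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, jitter_axes_frac = 0,
                jitter_center_mm = 0, ...)
}

# quick feature_table built from random numbers (no cohort generation);
# used by model-level tests that only need the schema
random_feature_table <- function(n, seed = 1, informative = FALSE) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 198, 2000, 600), n, 198,
              dimnames = list(NULL, dose_feature_names()))
  clin <- matrix(0, n, 16, dimnames = list(NULL, clinical_feature_names()))
  clin[, "male"] <- stats::rbinom(n, 1, 0.7)
  clin[, "age_gt_65"] <- stats::rbinom(n, 1, 0.3)
  clin[, "chemo"] <- stats::rbinom(n, 1, 0.6)
  clin[, paste0("vol_", c("iPG", "cPG", "iSMG", "cSMG", "iOC", "cOC"))] <-
    matrix(stats::runif(n * 6, 10, 200), n, 6)
  y <- if (informative) {
    # signal spread over one subvolume's nine Dx columns, as dose signal is
    sig <- rowMeans(scale(X[, paste0("cPG_mid_ant_D", seq(10, 90, 10))]))
    stats::rbinom(n, 1, stats::plogis(4 * sig))
  } else stats::rbinom(n, 1, 0.55)
  y[1] <- 1; y[2] <- 0   # both classes present
  rec <- ifelse(y == 1, stats::rbinom(n, 1, 0.7), NA)
  build_design_matrix(sprintf("P%03d", seq_len(n)), X, clin, y, rec)
}
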