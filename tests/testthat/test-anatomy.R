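test_that("laterality mapping assigns tumor-side organs ipsilateral and is an involution", {
  ss <- generate_anatomy(rigid_config(seed = 3), 11L)

  ss$tumor_laterality <- "left"
  roles <- map_laterality(ss)
  expect_identical(roles$iPG$roi_name, "PG_left")
  expect_identical(roles$cPG$roi_name, "PG_right")
  expect_identical(roles$iSMG$roi_name, "SMG_left")

  ss$tumor_laterality <- "right"
  roles_r <- map_laterality(ss)
  expect_identical(roles_r$iPG$roi_name, "PG_right")
  # swapping laterality swaps every role exactly
  expect_identical(roles$roles[names(roles_r$roles)],
                   ifelse(roles_r$roles == "ipsilateral", "contralateral", "ipsilateral"))

  ss$tumor_laterality <- NULL
  expect_error(map_laterality(ss), "laterality")
})

test_that("expand_mask is identity at margin 0, a superset otherwise, and monotone in margin", {
  g <- tiny_grid(c(20, 20, 20))
  m <- sphere_mask(g, c(9.5, 9.5, 9.5), 4)
  expect_identical(expand_mask(m, 0)$voxels, m$voxels)
  e2 <- expand_mask(m, 2)
  e4 <- expand_mask(m, 4)
  expect_true(all(e2$voxels[m$voxels]))        # superset of input
  expect_true(all(e4$voxels[e2$voxels]))       # monotone in margin
  empty <- roi_mask("none", g, array(FALSE, g$dims), allow_empty = TRUE)
  expect_error(expand_mask(empty, 3), "empty")
})

test_that("expanding a 10 mm digital sphere by 3 mm scales its volume like (13/10)^3", {
  g <- voxel_grid(c(40, 40, 40), c(1, 1, 1))
  m <- sphere_mask(g, c(19.5, 19.5, 19.5), 10)
  e <- expand_mask(m, 3)
  ratio <- sum(e$voxels) / sum(m$voxels)
  expect_lt(abs(ratio - (13 / 10)^3) / (13 / 10)^3, 0.05)
})

test_that("expansion respects anisotropic spacing", {
  g <- voxel_grid(c(30, 30, 12), c(1, 1, 3))
  m <- box_mask(g, c(14, 16), c(14, 16), c(5, 7))
  e <- expand_mask(m, 2)
  # 2 mm margin reaches 2 voxels in-plane but no further slices at 3 mm spacing
  expect_true(any(e$voxels[12, 15, 6]))
  expect_false(any(e$voxels[, , 4]))
  expect_false(any(e$voxels[, , 8]))
})

test_that("SI thirds cut a 9-slice box into exact 3-slice sections and partition any mask", {
  g <- tiny_grid(c(10, 10, 12))
  m <- box_mask(g, c(2, 8), c(2, 8), c(2, 10))   # 9 z-slices
  th <- split_si_thirds(m)
  per_slice <- 49L
  expect_identical(sum(th$inf$voxels), 3L * per_slice)
  expect_identical(sum(th$mid$voxels), 3L * per_slice)
  expect_identical(sum(th$sup$voxels), 3L * per_slice)

  # partition property on an irregular mask
  blob <- sphere_mask(g, c(4.5, 4.5, 6), 3.7)
  tb <- split_si_thirds(blob)
  uni <- tb$sup$voxels | tb$mid$voxels | tb$inf$voxels
  expect_identical(uni, blob$voxels)
  expect_false(any(tb$sup$voxels & tb$mid$voxels))
  expect_false(any(tb$mid$voxels & tb$inf$voxels))
  expect_false(any(tb$sup$voxels & tb$inf$voxels))
})

test_that("voxel centers exactly on an SI cut plane go to the more inferior section", {
  # z centers 0..6 (7 slices, spacing 1): cuts at exactly z = 2 and z = 4
  g <- tiny_grid(c(4, 4, 7))
  m <- box_mask(g, c(1, 4), c(1, 4), c(1, 7))
  th <- split_si_thirds(m)
  # brute-force voxel walk with the documented tie rule
  for (k in 1:7) {
    z <- k - 1
    expected <- if (z <= 2) "inf" else if (z <= 4) "mid" else "sup"
    for (s in c("inf", "mid", "sup"))
      expect_identical(any(th[[s]]$voxels[, , k]), s == expected,
                       label = sprintf("slice z=%d in %s", z, s))
  }
})

test_that("single-slice masks fall entirely into the middle section with a warning", {
  g <- tiny_grid()
  m <- box_mask(g, c(2, 5), c(2, 5), c(4, 4))
  expect_warning(th <- split_si_thirds(m), "single z-slice")
  expect_identical(th$mid$voxels, m$voxels)
  expect_identical(sum(th$sup$voxels) + sum(th$inf$voxels), 0L)
})

test_that("radial sectors of a centered cylinder are equal thirds and partition the gland", {
  g <- voxel_grid(c(81, 81, 10), c(0.5, 0.5, 1))
  cyl <- cylinder_mask(g, c(20, 20), 15, c(2, 9))
  sec <- split_radial_sectors(cyl, side = "left")
  total <- sum(cyl$voxels)
  for (s in c("med", "ant", "post"))
    expect_lt(abs(sum(sec[[s]]$voxels) / total - 1 / 3), 0.03)
  uni <- sec$med$voxels | sec$ant$voxels | sec$post$voxels
  expect_identical(uni, cyl$voxels)
  expect_false(any(sec$med$voxels & sec$ant$voxels))
  expect_false(any(sec$ant$voxels & sec$post$voxels))
})

test_that("radial sectors are mirror-equivariant across the midsagittal plane", {
  ss <- generate_anatomy(cohort_config(n_patients = 1, seed = 9), 21L)
  pg <- expand_mask(ss$PG_left, 3)
  sec_l <- split_radial_sectors(pg, "left")
  sec_r <- split_radial_sectors(mirror_mask(pg), "right")
  for (s in c("med", "ant", "post"))
    expect_identical(sec_r[[s]]$voxels, mirror_mask(sec_l[[s]])$voxels)
})

test_that("parotid partition yields 9 sectors that tile the expanded gland voxel-exactly", {
  ss <- generate_anatomy(cohort_config(n_patients = 1, seed = 5), 31L)
  pg <- expand_mask(ss$PG_right, 3)
  parts <- partition_parotid(pg, "right")
  expect_length(parts, 9L)
  expect_named(parts, as.vector(t(outer(c("sup", "mid", "inf"),
                                        c("med", "ant", "post"), paste, sep = "_"))))
  acc <- array(FALSE, dim = pg$grid$dims)
  count <- 0L
  for (p in parts) {
    expect_false(any(acc & p$voxels))   # pairwise disjoint
    acc <- acc | p$voxels
    count <- count + sum(p$voxels)
  }
  expect_identical(acc, pg$voxels)      # exact tiling
  expect_identical(count, sum(pg$voxels))
})

test_that("sup_med sector is nonempty and entirely above the upper SI cut", {
  ss <- generate_anatomy(rigid_config(seed = 2), 41L)
  pg <- expand_mask(ss$PG_left, 3)
  parts <- partition_parotid(pg, "left")
  expect_gt(sum(parts$sup_med$voxels), 0)
  z <- axis_coords(pg$grid, 3)
  zr <- range(z[apply(pg$voxels, 3, any)])
  cut2 <- zr[1] + 2 * (zr[2] - zr[1]) / 3
  idx <- which(parts$sup_med$voxels, arr.ind = TRUE)
  expect_true(all(z[idx[, 3]] > cut2))
})

test_that("oral-cavity surrogate halves are disjoint, organ-free and near-symmetric", {
  ss <- generate_anatomy(rigid_config(seed = 4), 51L)
  sv <- derive_subvolumes(ss)
  ioc <- sv$masks$iOC$voxels; coc <- sv$masks$cOC$voxels
  expect_false(any(ioc & coc))
  organs <- sv$expanded$iPG$voxels | sv$expanded$cPG$voxels |
    sv$expanded$iSMG$voxels | sv$expanded$cSMG$voxels | ss$mandible$voxels
  expect_false(any((ioc | coc) & organs))
  # zero-jitter anatomy is mirror symmetric: halves within 5%
  expect_lt(abs(sum(ioc) - sum(coc)) / sum(ioc | coc), 0.05)
  # clinical-scale order of magnitude: hundreds of cc
  expect_gt(mask_volume_cc(sv$masks$iOC), 30)
  expect_lt(mask_volume_cc(sv$masks$iOC), 500)
})

test_that("derive_subvolumes returns exactly 22 masks on the input grid, deterministically", {
  ss <- generate_anatomy(cohort_config(n_patients = 1, seed = 6), 61L)
  sv1 <- derive_subvolumes(ss)
  expect_length(sv1$masks, 22L)
  expect_setequal(names(sv1$masks), subvolume_names())
  for (m in sv1$masks) expect_true(xerosubvol:::grids_equal(m$grid, ss$grid))
  sv2 <- derive_subvolumes(ss)
  for (nm in names(sv1$masks))
    expect_identical(sv1$masks[[nm]]$voxels, sv2$masks[[nm]]$voxels)
})

test_that("the full subvolume set is mirror-equivariant with i/c roles swapped", {
  ss <- generate_anatomy(cohort_config(n_patients = 1, seed = 8), 71L)
  sv <- derive_subvolumes(ss)
  svm <- derive_subvolumes(mirror_structures(ss))
  for (nm in names(sv$masks))
    expect_identical(svm$masks[[nm]]$voxels, mirror_mask(sv$masks[[nm]])$voxels,
                     label = nm)
})
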