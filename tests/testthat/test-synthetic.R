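test_that("zero-jitter anatomy is exactly mirror-symmetric and all organs disjoint", {
  ss <- generate_anatomy(rigid_config(seed = 21), 7L)
  expect_identical(ss$PG_left$voxels, mirror_mask(ss$PG_right)$voxels)
  expect_identical(ss$SMG_left$voxels, mirror_mask(ss$SMG_right)$voxels)
  expect_identical(ss$mandible$voxels, mirror_mask(ss$mandible)$voxels)
})

test_that("organ masks are pairwise disjoint for arbitrary seeds", {
  cfg <- cohort_config(n_patients = 1, seed = 33)
  for (s in c(5L, 901L, 77L)) {
    ss <- generate_anatomy(cfg, s)
    organs <- c("PG_left", "PG_right", "SMG_left", "SMG_right", "mandible")
    for (i in seq_along(organs)) for (j in seq_along(organs)) if (i < j)
      expect_identical(sum(ss[[organs[i]]]$voxels & ss[[organs[j]]]$voxels), 0L,
                       label = paste(organs[i], organs[j], "seed", s))
  }
})

test_that("parotid voxel volume matches the analytic ellipsoid volume within 10%", {
  # semi-axes 15 x 20 x 25 mm at 2 mm isotropic spacing, no jitter
  ss <- generate_anatomy(rigid_config(seed = 1), 13L)
  analytic_cc <- 4 / 3 * pi * 15 * 20 * 25 / 1000   # 31.4 cc
  for (pg in c("PG_left", "PG_right"))
    expect_lt(abs(mask_volume_cc(ss[[pg]]) - analytic_cc) / analytic_cc, 0.10)
})

test_that("noise-free dose peaks at the prescription on target and favors the ipsilateral side", {
  cfg <- rigid_config(seed = 2, dose_noise_sd_cgy = 0)
  ss <- generate_anatomy(cfg, 17L)
  d <- generate_dose(ss, cfg, 18L)
  target <- attr(d, "target_mm"); sigma <- attr(d, "sigma_mm")
  # the kernel evaluated at its own center is exactly the prescription
  expect_identical(cfg$prescription_cgy * exp(-sum((target - target)^2)), 7000)
  expect_lte(max(d$values), cfg$prescription_cgy)
  # the voxel nearest the target carries (almost) the prescription
  g <- d$grid
  nearest <- vapply(1:3, function(ax) which.min(abs(axis_coords(g, ax) - target[ax])),
                    integer(1))
  analytic <- cfg$prescription_cgy *
    prod(exp(-((vapply(1:3, function(ax) axis_coords(g, ax)[nearest[ax]], numeric(1)) -
                  target)^2) / (2 * sigma^2)))
  expect_equal(d$values[nearest[1], nearest[2], nearest[3]], analytic, tolerance = 1e-12)

  roles <- map_laterality(ss)
  expect_gte(mean(d$values[roles$iPG$voxels]), mean(d$values[roles$cPG$voxels]))
})

test_that("pooled voxel dose of a 20-patient cohort stays within 0-7900 cGy", {
  cfg <- cohort_config(n_patients = 20, seed = 19)
  rng <- c(Inf, -Inf)
  for (i in 1:20) {
    ss <- generate_anatomy(cfg, xerosubvol:::patient_seed_base(cfg$seed, i) + 1L)
    d <- generate_dose(ss, cfg, xerosubvol:::patient_seed_base(cfg$seed, i) + 2L)
    rng <- c(min(rng[1], min(d$values)), max(rng[2], max(d$values)))
  }
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 7900)
})

test_that("cohort generation is bit-identical under an identical config and seed", {
  cfg <- cohort_config(n_patients = 4, seed = 91)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cohort_config(n_patients = 4, seed = 91))
  expect_identical(lapply(c1$patients, `[[`, "features"),
                   lapply(c2$patients, `[[`, "features"))
  expect_identical(lapply(c1$patients, function(p) p$timeline$ctcae_grade),
                   lapply(c2$patients, function(p) p$timeline$ctcae_grade))
  expect_identical(cohort_feature_table(c1), cohort_feature_table(c2))
})

test_that("timelines realize the latent labels: derive_outcomes round-trips exactly", {
  cfg <- cohort_config(n_patients = 14, seed = 23)
  co <- generate_cohort(cfg)
  for (p in co$patients) {
    lab <- derive_outcomes(p$timeline)
    expect_false(lab$excluded)
    expect_identical(lab$injury, p$latent$injury, label = p$patient_id)
    expect_identical(lab$recovery, p$latent$recovery, label = p$patient_id)
    expect_true(548L %in% p$timeline$days_post_rt)   # 18-month visit always present
  }
})

test_that("a degenerate injury intercept produces no injuries and undefined recoveries", {
  cfg <- cohort_config(n_patients = 6, seed = 3,
                       intercepts = c(injury = -Inf, recovery = 0))
  co <- generate_cohort(cfg)
  inj <- vapply(co$patients, function(p) p$latent$injury, numeric(1))
  expect_true(all(inj == 0))
  expect_true(all(is.na(vapply(co$patients, function(p) p$latent$recovery, numeric(1)))))
})

test_that("the null mechanism (zero weights, zero intercepts) yields ~50% injury", {
  cfg <- cohort_config(n_patients = 120, seed = 29,
                       effect_subvolumes = list(injury = numeric(0), recovery = numeric(0)),
                       intercepts = c(injury = 0, recovery = 0))
  co <- generate_cohort(cfg)
  prev <- mean(vapply(co$patients, function(p) p$latent$injury, numeric(1)))
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 120))   # within 3 binomial SEs
})

test_that("configuration errors are caught before any generation", {
  expect_error(cohort_config(10, grid_shape = c(20, 20, 12)), "grid too small")
  expect_error(cohort_config(10, effect_subvolumes =
                               list(injury = c(nonesuch_D10 = 1), recovery = numeric(0))),
               "unknown dose feature")
  bad_mix <- default_clinical_mix(); bad_mix$race <- c(white = 0.5, african_american = 0.2, other = 0.2)
  expect_error(cohort_config(10, clinical_mix = bad_mix), "sum to 1")
  expect_identical(planted_subvolumes(cohort_config(2), "injury"),
                   c("cPG_mid_ant", "cPG_mid_post", "cOC"))
})
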