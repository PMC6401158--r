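test_that("cumulative DVH is the exact descending voxel-dose sample", {
  g <- tiny_grid(c(2, 2, 1))
  m <- roi_mask("m", g, array(TRUE, g$dims))
  d <- dose_grid(g, array(c(10, 30, 20, 40), g$dims))
  dvh <- cumulative_dvh(m, d)
  expect_identical(dvh$sample, c(40, 30, 20, 10))
  expect_identical(dvh$n_voxels, 4L)

  u <- dose_grid(g, array(5000, g$dims))
  expect_true(all(cumulative_dvh(m, u)$sample == 5000))

  g2 <- tiny_grid(c(2, 2, 1), spacing = c(2, 2, 2))
  expect_error(cumulative_dvh(roi_mask("m", g2, array(TRUE, g2$dims)), d), "grid mismatch")
})

test_that("dose_at_volume matches the hand-computed interpolation and stays in range", {
  dvh <- structure(list(subvolume = "s", sample = c(40, 30, 20, 10), n_voxels = 4L),
                   class = "dvh_curve")
  expect_equal(dose_at_volume(dvh, 50), 25)       # midpoint of ranks 1 and 2
  expect_equal(dose_at_volume(dvh, 10), 37)       # 0.3 of the way from 40 to 30
  u <- structure(list(subvolume = "s", sample = rep(1234, 7), n_voxels = 7L),
                 class = "dvh_curve")
  for (x in seq(10, 90, 10)) expect_equal(dose_at_volume(u, x), 1234)
  expect_error(dose_at_volume(dvh, 0), "strictly between")
  expect_error(dose_at_volume(dvh, 100), "strictly between")
})

test_that("dose_at_volume agrees with an independent quantile oracle to 1e-9", {
  set.seed(42)
  for (case in 1:1000) {
    n <- sample(1:60, 1)
    s <- sort(round(stats::runif(n, 0, 8000), 3), decreasing = TRUE)
    dvh <- structure(list(subvolume = "s", sample = s, n_voxels = n),
                     class = "dvh_curve")
    x <- stats::runif(1, 0.5, 99.5)
    # independent route: type-7 quantile of the ascending sample at 1 - x/100
    oracle <- unname(stats::quantile(s, probs = 1 - x / 100, type = 7, names = FALSE))
    expect_lt(abs(dose_at_volume(dvh, x) - oracle), 1e-9)
  }
})

test_that("Dx is non-increasing in x on random samples", {
  set.seed(7)
  for (case in 1:50) {
    s <- sort(stats::rexp(sample(2:40, 1), 1 / 2000), decreasing = TRUE)
    dvh <- structure(list(subvolume = "s", sample = s, n_voxels = length(s)),
                     class = "dvh_curve")
    dx <- vapply(seq(10, 90, 10), function(x) dose_at_volume(dvh, x), numeric(1))
    expect_true(all(diff(dx) <= 1e-12))
  }
})

test_that("feature extraction yields 198 deterministic columns with expected invariances", {
  ss <- generate_anatomy(cohort_config(n_patients = 1, seed = 12), 81L)
  sv <- derive_subvolumes(ss)
  g <- ss$grid

  u <- dose_grid(g, array(4321, g$dims))
  f_u <- extract_dose_features(sv, u)
  expect_length(f_u, 198L)
  expect_identical(names(f_u), dose_feature_names())
  expect_true(all(f_u == 4321))                     # constant field

  cfg <- cohort_config(n_patients = 1, seed = 12)
  d <- generate_dose(ss, cfg, 82L)
  f1 <- extract_dose_features(sv, d)
  d2 <- dose_grid(g, d$values * 2)
  f2 <- extract_dose_features(sv, d2)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)       # positive homogeneity
  expect_identical(f1, extract_dose_features(sv, d))  # determinism
})

test_that("clinical encoding uses reference cells and completes the 214-predictor schema", {
  vols <- c(iPG = 60, cPG = 58, iSMG = 20, cSMG = 21, iOC = 178, cOC = 176)
  ref <- clinical_record(0, "male", "white", 0, "others", vols)
  enc <- encode_clinical(ref)
  expect_length(enc, 16L)
  expect_identical(names(enc), clinical_feature_names())
  dummies <- setdiff(clinical_feature_names(),
                     c("male", paste0("vol_", names(vols))))
  expect_true(all(enc[dummies] == 0))
  expect_identical(unname(enc[paste0("vol_", names(vols))]), unname(vols))

  other <- clinical_record(1, "female", "african_american", 1, "oropharynx", vols)
  e2 <- encode_clinical(other)
  expect_identical(sum(e2[c("race_african_american", "race_other")]), 1)
  expect_identical(sum(e2[paste0("site_", c("nasopharynx", "oral_cavity", "oropharynx",
                                            "hypopharynx", "larynx"))]), 1)
  expect_error(clinical_record(0, "male", "martian", 0, "others", vols), "race")
  expect_error(clinical_record(0, "male", "white", 0, "elbow", vols), "site")

  expect_identical(length(dose_feature_names()) + length(clinical_feature_names()), 214L)
})

test_that("design matrix joins features with labels and restricts the recovery population", {
  tab <- random_feature_table(40, seed = 3)
  expect_identical(ncol(tab), 1L + 214L + 2L)       # id + predictors + 2 labels
  pop_inj <- model_population(tab, "injury")
  pop_rec <- model_population(tab, "recovery")
  expect_identical(nrow(pop_inj$X), 40L)
  expect_identical(nrow(pop_rec$X), sum(tab$injury == 1))
  expect_true(all(pop_rec$y %in% c(0, 1)))

  # row order invariance
  perm <- sample(nrow(tab))
  tab2 <- build_design_matrix(tab$patient_id[perm],
                              as.matrix(tab[perm, dose_feature_names()]),
                              as.matrix(tab[perm, clinical_feature_names()]),
                              tab$injury[perm], tab$recovery[perm])
  expect_equal(tab2[order(tab2$patient_id), ], tab[order(tab$patient_id), ],
               ignore_attr = TRUE)

  expect_error(build_design_matrix(rep("P1", 2), matrix(0, 2, 198), matrix(0, 2, 16),
                                   c(1, 0), c(1, NA)), "duplicated")
  expect_error(build_design_matrix(c("a", "b"),
                                   matrix(0, 2, 198, dimnames = list(NULL, dose_feature_names())),
                                   matrix(0, 2, 16, dimnames = list(NULL, clinical_feature_names())),
                                   c(0, 1), c(1, 1)), "undefined")
})

test_that("deposited feature CSVs load with case-insensitive headers", {
  tab <- random_feature_table(8, seed = 5)
  path <- tempfile(fileext = ".csv")
  out <- tab
  names(out) <- toupper(names(out))   # mangle case
  utils::write.csv(out, path, row.names = FALSE)
  back <- read_deposited_features(path)
  expect_s3_class(back, "feature_table")
  expect_equal(as.matrix(back[, dose_feature_names()]),
               as.matrix(tab[, dose_feature_names()]), ignore_attr = TRUE)
  expect_identical(back$injury, tab$injury)
})
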