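tl <- function(days, grades, id = "P1") assessment_timeline(id, days, grades)

test_that("injury and recovery labels follow the 6- and 18-month window definitions", {
  # never above grade 1: no injury, recovery undefined
  lab <- derive_outcomes(tl(c(42, 180, 548), c(0, 1, 1)))
  expect_identical(lab$injury, 0); expect_true(is.na(lab$recovery))

  # grade 2 at day 90 resolving to 1 by day 540: injury then recovery
  lab <- derive_outcomes(tl(c(90, 540), c(2, 1)))
  expect_identical(lab$injury, 1); expect_identical(lab$recovery, 1)

  # sustained grade 2 through day 540: injury without recovery
  lab <- derive_outcomes(tl(c(90, 540), c(2, 2)))
  expect_identical(lab$injury, 1); expect_identical(lab$recovery, 0)

  # boundary: day 183 counts as within 6 months; day 184 does not
  expect_identical(derive_outcomes(tl(c(183, 548), c(2, 0)))$injury, 1)
  expect_identical(derive_outcomes(tl(c(184, 548), c(2, 0)))$injury, 0)

  # recovery judged by the LAST assessment inside 548 days
  lab <- derive_outcomes(tl(c(90, 400, 548), c(2, 1, 2)))
  expect_identical(lab$recovery, 0)

  # empty or out-of-window timelines signal exclusion, not an error
  expect_true(derive_outcomes(tl(integer(0), integer(0)))$excluded)
  expect_true(derive_outcomes(tl(600, 2))$excluded)
})

test_that("prevalence curve counts grade >= 2 per window over assessed patients only", {
  quiet <- lapply(1:10, function(i) tl(visit_schedule(), rep(0L, 7), sprintf("q%d", i)))
  pc <- prevalence_curve(quiet)
  expect_true(all(pc$prevalence == 0))

  # 29 of 50 patients with grade 2 at the on-treatment visit -> 0.58
  mixed <- lapply(1:50, function(i)
    tl(visit_schedule(), c(if (i <= 29) 2L else 0L, rep(0L, 6)), sprintf("m%d", i)))
  pm <- prevalence_curve(mixed)
  expect_equal(pm$prevalence[pm$window == "OTV"], 0.58)
  expect_equal(pm$n_assessed[pm$window == "OTV"], 50L)

  # patient order must not matter
  expect_identical(prevalence_curve(rev(mixed)), pm)

  # a window nobody attends is NA
  sparse <- list(tl(c(42, 548), c(0, 0)))
  ps <- prevalence_curve(sparse)
  expect_true(is.na(ps$prevalence[ps$window == "m6"]))
})

test_that("group summaries report per-group mean and sample-sd coefficient of variation", {
  tab <- random_feature_table(30, seed = 9)
  # two identical injured+recovered patients: cv must be 0
  tab2 <- tab
  tab2[2, dose_feature_names()] <- tab2[1, dose_feature_names()]
  tab2$injury[1:2] <- 1; tab2$recovery[1:2] <- 1
  tab2$injury[-(1:2)] <- 0; tab2$recovery[-(1:2)] <- NA
  gs <- group_summaries(tab2)
  rec_rows <- gs[gs$group == "injury_recovery", ]
  expect_true(all(rec_rows$cv == 0))
  expect_identical(unique(rec_rows$n), 2L)

  # hand-computed case: mean {1000, 3000} = 2000, cv = sqrt(2)*1000/2000
  tab3 <- tab2
  tab3[1, dose_feature_names()] <- 1000
  tab3[2, dose_feature_names()] <- 3000
  gs3 <- group_summaries(tab3)
  r3 <- gs3[gs3$group == "injury_recovery", ]
  expect_equal(unique(r3$mean), 2000)
  expect_equal(unique(r3$cv), sqrt(2) * 1000 / 2000, tolerance = 1e-12)

  # group means bounded by member extremes
  no_x <- gs[gs$group == "no_xerostomia", ]
  M <- as.matrix(tab2[tab2$injury == 0, dose_feature_names()])
  expect_true(all(no_x$mean >= apply(M, 2, min) - 1e-9))
  expect_true(all(no_x$mean <= apply(M, 2, max) + 1e-9))
})

test_that("max-T Monte-Carlo p-values agree with exact enumeration on a 4-vs-4 toy", {
  set.seed(101)
  n <- 8; p <- 6
  X <- matrix(stats::rnorm(n * p, 1000, 300), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)

  # independent oracle: enumerate all choose(8,4) = 70 class assignments
  tstat <- function(yy) {
    m1 <- colMeans(X[yy == 1, ]); m0 <- colMeans(X[yy == 0, ])
    v1 <- apply(X[yy == 1, ], 2, stats::var); v0 <- apply(X[yy == 0, ], 2, stats::var)
    sp2 <- (3 * v1 + 3 * v0) / 6
    (m1 - m0) / sqrt(sp2 * (1 / 4 + 1 / 4))
  }
  t_obs <- tstat(y)
  combs <- utils::combn(n, 4)
  maxima <- apply(combs, 2, function(idx) {
    yy <- numeric(n); yy[idx] <- 1; max(tstat(yy))
  })
  p_exact <- vapply(t_obs, function(t) mean(maxima >= t - 1e-12), numeric(1))

  res <- maxT_permutation_test(X, y, n_perm = 2000, seed = 5)
  expect_equal(res$T, unname(t_obs), tolerance = 1e-9)
  expect_true(all(abs(res$p_adjusted - p_exact) < 0.05))
})

test_that("max-T adjusted p-values dominate the single-feature permutation p-values", {
  set.seed(11)
  X <- matrix(stats::rnorm(40 * 25), 40, 25)
  y <- rep(c(1, 0), 20)
  res <- maxT_permutation_test(X, y, n_perm = 300, seed = 2)
  expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-12))
  expect_true(all(res$p_adjusted > 0 & res$p_adjusted <= 1))
})

test_that("constant features are flagged and carry a zero statistic", {
  set.seed(4)
  X <- cbind(const = rep(3, 30), noise = stats::rnorm(30))
  y <- rep(c(1, 0), 15)
  expect_warning(res <- maxT_permutation_test(X, y, n_perm = 100, seed = 1),
                 "constant")
  expect_identical(res$T[res$feature == "const"], 0)
})

test_that("permutation results are reproducible from the seed and respect direction", {
  set.seed(6)
  X <- matrix(stats::rnorm(30 * 10), 30, 10)
  y <- rep(c(1, 0), 15)
  r1 <- maxT_permutation_test(X, y, n_perm = 200, seed = 42)
  r2 <- maxT_permutation_test(X, y, n_perm = 200, seed = 42)
  expect_identical(r1$p_adjusted, r2$p_adjusted)
  r_less <- maxT_permutation_test(X, y, n_perm = 200, direction = "less", seed = 42)
  expect_equal(r_less$T, -r1$T, tolerance = 1e-12)
})
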