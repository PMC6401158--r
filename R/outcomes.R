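#' Longitudinal xerostomia assessment timeline
#'
#' CTCAE xerostomia grades (0-3) recorded at visits after the end of
#' radiotherapy. Grade >= 2 is clinically significant xerostomia.
#'
#' @param patient_id patient identifier.
#' @param days_post_rt integer vector of assessment days (>= 0), strictly
#'   increasing.
#' @param ctcae_grade integer vector of grades in {0, 1, 2, 3}.
#' @return An object of class `assessment_timeline`.
#' @export
assessment_timeline <- function(patient_id, days_post_rt, ctcae_grade) {
  days_post_rt <- as.integer(days_post_rt)
  ctcae_grade <- as.integer(ctcae_grade)
  if (length(days_post_rt) != length(ctcae_grade))
    stop("days and grades must have equal length")
  if (length(days_post_rt) > 0L) {
    if (any(days_post_rt < 0L)) stop("days_post_rt must be >= 0")
    if (any(diff(days_post_rt) <= 0L)) stop("days_post_rt must be strictly increasing")
    if (any(!ctcae_grade %in% 0:3)) stop("ctcae_grade must be in 0..3")
  }
  structure(list(patient_id = patient_id, days_post_rt = days_post_rt,
                 ctcae_grade = ctcae_grade),
            class = "assessment_timeline")
}

#' Derive injury and recovery labels from a timeline
#'
#' Injury is any grade >= 2 within 6 months (183 days) of radiotherapy.
#' Recovery — defined only for injured patients — is a subsequent reduction
#' of the grade below 2 within 18 months (548 days), judged by the last
#' assessment inside that window. A patient with no usable assessment in the
#' 18-month window yields an exclusion signal rather than an error.
#'
#' @param timeline an `assessment_timeline`.
#' @param injury_days injury window in days, default 183 (6 months).
#' @param recovery_days recovery window in days, default 548 (18 months).
#' @return List of class `outcome_labels` with `injury` (0/1), `recovery`
#'   (0/1, `NA` when not injured) and `excluded` (TRUE when the timeline has
#'   no assessment inside the 18-month window).
#' @export
derive_outcomes <- function(timeline, injury_days = 183L, recovery_days = 548L) {
  stopifnot(inherits(timeline, "assessment_timeline"))
  d <- timeline$days_post_rt
  g <- timeline$ctcae_grade
  in_window <- d <= recovery_days
  if (length(d) == 0L || !any(in_window)) {
    return(structure(list(injury = NA_real_, recovery = NA_real_, excluded = TRUE),
                     class = "outcome_labels"))
  }
  injury <- as.numeric(any(g >= 2L & d <= injury_days))
  recovery <- NA_real_
  if (injury == 1) {
    last <- max(which(in_window))
    recovery <- as.numeric(g[last] < 2L)
  }
  structure(list(injury = injury, recovery = recovery, excluded = FALSE),
            class = "outcome_labels")
}

#' Default follow-up windows for the prevalence curve
#'
#' Day intervals capturing the on-treatment visit (OTV, the ~6-week visit)
#' and the 3, 6, 9, 12 and 18 month follow-ups.
#' @return data.frame with columns `window`, `lo`, `hi` (days, inclusive).
#' @export
default_visit_windows <- function() {
  data.frame(window = c("OTV", "m3", "m6", "m9", "m12", "m18"),
             lo = c(0L, 64L, 136L, 226L, 316L, 494L),
             hi = c(63L, 135L, 225L, 315L, 410L, 610L),
             stringsAsFactors = FALSE)
}

#' Prevalence of grade >= 2 xerostomia per follow-up window
#'
#' For each window, the fraction of assessed patients with any grade >= 2
#' assessment inside the window. The denominator is the number of patients
#' with at least one assessment in the window; a window with no assessed
#' patients yields `NA`.
#'
#' @param timelines list of `assessment_timeline`s.
#' @param visit_windows data.frame as from [default_visit_windows()].
#' @return data.frame with `window`, `n_assessed`, `n_grade2plus`, `prevalence`.
#' @export
prevalence_curve <- function(timelines, visit_windows = default_visit_windows()) {
  if (length(timelines) == 0L) stop("no timelines supplied")
  res <- visit_windows
  res$n_assessed <- 0L; res$n_grade2plus <- 0L
  for (tl in timelines) {
    stopifnot(inherits(tl, "assessment_timeline"))
    for (k in seq_len(nrow(res))) {
      inw <- tl$days_post_rt >= res$lo[k] & tl$days_post_rt <= res$hi[k]
      if (any(inw)) {
        res$n_assessed[k] <- res$n_assessed[k] + 1L
        if (any(tl$ctcae_grade[inw] >= 2L))
          res$n_grade2plus[k] <- res$n_grade2plus[k] + 1L
      }
    }
  }
  res$prevalence <- ifelse(res$n_assessed > 0L, res$n_grade2plus / res$n_assessed, NA_real_)
  res[, c("window", "lo", "hi", "n_assessed", "n_grade2plus", "prevalence")]
}

#' Per-group mean and coefficient of variation of the dose features
#'
#' Splits the cohort into the three outcome groups — no xerostomia, injury
#' followed by recovery, injury without recovery — and reports, per dose
#' feature and group, the mean and the coefficient of variation (sample
#' standard deviation divided by mean; undefined when the mean is zero).
#'
#' @param table a `feature_table`.
#' @return data.frame with columns `feature`, `group`, `n`, `mean`, `cv`.
#' @export
group_summaries <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  groups <- list(
    no_xerostomia   = table$injury == 0,
    injury_recovery = table$injury == 1 & !is.na(table$recovery) & table$recovery == 1,
    injury_no_recovery = table$injury == 1 & !is.na(table$recovery) & table$recovery == 0
  )
  feats <- dose_feature_names()
  out <- list()
  for (gname in names(groups)) {
    rows <- groups[[gname]]
    if (!any(rows)) next
    M <- as.matrix(table[rows, feats, drop = FALSE])
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    cv <- ifelse(mu == 0, NA_real_, sdv / mu)
    out[[gname]] <- data.frame(feature = feats, group = gname, n = sum(rows),
                               mean = unname(mu), cv = unname(cv),
                               stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
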