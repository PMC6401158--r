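#' Follow-up visit schedule of the synthetic cohort (days post-RT)
#'
#' A 6-week visit followed by 3-monthly visits through 18 months, mirroring
#' guideline-style head-and-neck follow-up. The 18-month assessment (day 548)
#' is always present, so no synthetic patient is excluded for a missing
#' 18-month score.
#' @export
visit_schedule <- function() c(42L, 90L, 180L, 270L, 365L, 450L, 548L)

#' Configuration of the synthetic xerostomia cohort
#'
#' Defines the study conditions under which synthetic patients are generated:
#' grid geometry, anatomy jitter, the Gaussian dose field, clinical covariate
#' mix, and the logistic dose-to-outcome mechanism. Dose features enter the
#' outcome logits divided by `dose_scale_cgy` (default 1000), so a weight of
#' 1 corresponds to one unit of log-odds per 10 Gy.
#'
#' @param n_patients number of patients.
#' @param seed master seed; every patient's draws derive from (seed, index).
#' @param grid_shape integer length-3 array dims, default c(64, 64, 48).
#' @param spacing_mm voxel spacing, default c(2, 2, 2) mm.
#' @param prescription_cgy peak (prescription) dose of the field, default 7000.
#' @param dose_sigma_mm Gaussian kernel width, default 30 mm.
#' @param dose_noise_sd_cgy additive noise sd (truncated at 3 sd), default 150.
#' @param target_jitter_mm per-patient uniform jitter of the dose target
#'   position, default 8 mm per axis.
#' @param sigma_jitter_frac per-patient relative jitter of the kernel width,
#'   default 0.25.
#' @param jitter_axes_frac per-patient relative jitter of gland semi-axes,
#'   default 0.15.
#' @param jitter_center_mm per-patient jitter of gland centers, default 4 mm.
#' @param effect_subvolumes list with `injury` and `recovery`: named numeric
#'   weights on dose-feature columns (e.g. `cPG_mid_ant_D30`) entering the
#'   respective logits.
#' @param clinical_effects list with `injury` and `recovery`: named numeric
#'   weights on encoded clinical columns; defaults to none (all signal in
#'   dose).
#' @param intercepts named numeric: `injury` and `recovery` logit intercepts.
#' @param clinical_mix category probabilities for the covariate draws.
#' @param onset_probs probabilities of the first grade>=2 visit among the
#'   injured falling at day 42, 90 or 180.
#' @param dose_scale_cgy divisor applied to cGy features inside the logits.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          grid_shape = c(64L, 64L, 48L),
                          spacing_mm = c(2, 2, 2),
                          prescription_cgy = 7000,
                          dose_sigma_mm = 30,
                          dose_noise_sd_cgy = 150,
                          target_jitter_mm = 8,
                          sigma_jitter_frac = 0.25,
                          jitter_axes_frac = 0.15,
                          jitter_center_mm = 4,
                          effect_subvolumes = default_effect_subvolumes(),
                          clinical_effects = list(injury = numeric(0), recovery = numeric(0)),
                          intercepts = c(injury = -3.05, recovery = 6.52),
                          clinical_mix = default_clinical_mix(),
                          onset_probs = c(`42` = 0.85, `90` = 0.10, `180` = 0.05),
                          dose_scale_cgy = 1000) {
  stopifnot(n_patients >= 1, length(grid_shape) == 3L, length(spacing_mm) == 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  if (dose_sigma_mm <= 0) stop("dose_sigma_mm must be positive")
  if (dose_noise_sd_cgy < 0) stop("dose_noise_sd_cgy must be nonnegative")
  for (nm in c("injury", "recovery")) {
    w <- effect_subvolumes[[nm]]
    if (length(w)) {
      if (any(!is.finite(w))) stop("effect weights must be finite")
      bad <- setdiff(names(w), dose_feature_names())
      if (length(bad))
        stop(sprintf("effect_subvolumes (%s) names unknown dose feature(s): %s",
                     nm, paste(bad, collapse = ", ")))
    }
    ce <- clinical_effects[[nm]]
    if (length(ce)) {
      bad <- setdiff(names(ce), clinical_feature_names())
      if (length(bad))
        stop(sprintf("clinical_effects (%s) names unknown column(s): %s",
                     nm, paste(bad, collapse = ", ")))
    }
  }
  if (!all(c("injury", "recovery") %in% names(intercepts)))
    stop("intercepts must name injury and recovery")
  for (mx in list(clinical_mix$race, clinical_mix$site, clinical_mix$laterality)) {
    if (abs(sum(mx) - 1) > 1e-8) stop("categorical mix probabilities must sum to 1")
  }
  if (abs(sum(onset_probs) - 1) > 1e-8) stop("onset_probs must sum to 1")

  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    prescription_cgy = prescription_cgy, dose_sigma_mm = dose_sigma_mm,
    dose_noise_sd_cgy = dose_noise_sd_cgy, target_jitter_mm = target_jitter_mm,
    sigma_jitter_frac = sigma_jitter_frac, jitter_axes_frac = jitter_axes_frac,
    jitter_center_mm = jitter_center_mm, effect_subvolumes = effect_subvolumes,
    clinical_effects = clinical_effects, intercepts = intercepts,
    clinical_mix = clinical_mix, onset_probs = onset_probs,
    dose_scale_cgy = dose_scale_cgy
  ), class = "cohort_config")
  check_grid_capacity(cfg)
  cfg
}

#' Default dose-to-outcome effect weights
#'
#' The planted mechanism mirrors the qualitative pattern the pipeline is
#' meant to detect: injury driven by high-dose features of the contralateral
#' middle parotid and oral cavity; recovery impaired (negative weights) by
#' dose to the superior parotid sectors and contralateral oral cavity.
#' @export
default_effect_subvolumes <- function() {
  list(
    injury = c(cPG_mid_ant_D30 = 1.3, cPG_mid_post_D30 = 0.9, cOC_D10 = 0.7),
    recovery = c(cPG_sup_ant_D50 = -1.2, iPG_sup_post_D50 = -0.9, cOC_D30 = -0.7)
  )
}

#' Default clinical covariate mix (head-and-neck cohort proportions)
#' @export
default_clinical_mix <- function() {
  list(age_gt_65 = 72 / 258, male = 202 / 258,
       race = c(white = 206 / 258, african_american = 46 / 258, other = 6 / 258),
       chemo = 175 / 258,
       site = c(nasopharynx = 10 / 258, oral_cavity = 66 / 258,
                oropharynx = 100 / 258, hypopharynx = 6 / 258,
                larynx = 35 / 258, others = 41 / 258),
       laterality = c(left = 0.5, right = 0.5))
}

# nominal anatomy layout in mm, relative to the grid's physical extent
anatomy_layout <- function(grid) {
  ext <- (grid$dims - 1) * grid$spacing_mm
  x_mid <- ext[1] / 2
  list(
    x_mid = x_mid,
    pg_axes = c(15, 20, 25), pg_dx = 38, pg_y = 70, pg_z = 58,
    smg_axes = c(11, 13, 14), smg_dx = 20, smg_y = 52, smg_z = 30,
    mand_center_y = 46, mand_radius = 28, mand_halfwidth = 5,
    mand_z = c(28, 56), mand_halfangle = 115
  )
}

check_grid_capacity <- function(cfg) {
  g <- voxel_grid(cfg$grid_shape, cfg$spacing_mm)
  ext <- (g$dims - 1) * g$spacing_mm
  lay <- anatomy_layout(g)
  pad <- cfg$jitter_center_mm + 3  # center jitter + expansion margin
  reach <- lay$pg_axes * (1 + cfg$jitter_axes_frac) + pad
  lo <- c(lay$x_mid - lay$pg_dx, lay$pg_y, lay$pg_z) - reach
  hi <- c(lay$x_mid + lay$pg_dx, lay$pg_y, lay$pg_z) + reach
  if (any(lo < 0) || any(hi > ext))
    stop("grid too small to place parotid glands (with jitter and 3 mm margin)")
  reach_s <- lay$smg_axes * (1 + cfg$jitter_axes_frac) + pad
  lo <- c(lay$x_mid - lay$smg_dx, lay$smg_y, lay$smg_z) - reach_s
  hi <- c(lay$x_mid + lay$smg_dx, lay$smg_y, lay$smg_z) + reach_s
  if (any(lo < 0) || any(hi > ext))
    stop("grid too small to place submandibular glands (with jitter and 3 mm margin)")
  if (lay$mand_z[2] > ext[3] ||
      lay$mand_center_y + lay$mand_radius + lay$mand_halfwidth > ext[2])
    stop("grid too small to place the mandible arc")
  invisible(TRUE)
}

ellipsoid_mask <- function(grid, center, axes) {
  qx <- ((axis_coords(grid, 1) - center[1]) / axes[1])^2
  qy <- ((axis_coords(grid, 2) - center[2]) / axes[2])^2
  qz <- ((axis_coords(grid, 3) - center[3]) / axes[3])^2
  out <- array(FALSE, dim = grid$dims)
  ix <- which(qx <= 1); iy <- which(qy <= 1); iz <- which(qz <= 1)
  if (length(ix) && length(iy) && length(iz)) {
    q <- outer(outer(qx[ix], qy[iy], "+"), qz[iz], "+")
    out[ix, iy, iz] <- q <= 1
  }
  out
}

#' Generate one patient's anatomy
#'
#' Places two parotid ellipsoids lateral-posterior to a mandible arc, two
#' submandibular ellipsoids inferior-medial to the parotids, and the mandible
#' arc between them, with per-patient uniform jitter on gland semi-axes and
#' centers. Organ masks are made pairwise disjoint by construction (mandible
#' takes precedence over parotids, which take precedence over submandibular
#' glands). Tumor laterality is drawn from the configured mix.
#'
#' @param config a `cohort_config`.
#' @param patient_seed integer seed for this patient's anatomy draws.
#' @return A `structure_set`.
#' @export
generate_anatomy <- function(config, patient_seed) {
  g <- voxel_grid(config$grid_shape, config$spacing_mm)
  ext <- (g$dims - 1) * g$spacing_mm
  lay <- anatomy_layout(g)
  jf <- config$jitter_axes_frac
  jc <- config$jitter_center_mm

  with_local_seed(patient_seed, {
    laterality <- sample(names(config$clinical_mix$laterality), 1,
                         prob = config$clinical_mix$laterality)
    jit <- function(axes, center) {
      list(axes = axes * (1 + stats::runif(3, -jf, jf)),
           center = center + stats::runif(3, -jc, jc))
    }
    pg_l  <- jit(lay$pg_axes,  c(lay$x_mid + lay$pg_dx,  lay$pg_y,  lay$pg_z))
    pg_r  <- jit(lay$pg_axes,  c(lay$x_mid - lay$pg_dx,  lay$pg_y,  lay$pg_z))
    smg_l <- jit(lay$smg_axes, c(lay$x_mid + lay$smg_dx, lay$smg_y, lay$smg_z))
    smg_r <- jit(lay$smg_axes, c(lay$x_mid - lay$smg_dx, lay$smg_y, lay$smg_z))
  })

  specs <- list(PG_left = pg_l, PG_right = pg_r, SMG_left = smg_l, SMG_right = smg_r)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (any(s$center - s$axes - 3 < 0) || any(s$center + s$axes + 3 > ext))
      stop(sprintf("grid too small to place %s (with its 3 mm margin)", nm))
  }

  # mandible: axial arc (horseshoe) of fixed geometry between the glands
  xc <- axis_coords(g, 1); yc <- axis_coords(g, 2); zc <- axis_coords(g, 3)
  dx <- outer(xc - lay$x_mid, rep(1, g$dims[2]))
  dy <- outer(rep(1, g$dims[1]), yc - lay$mand_center_y)
  r2d <- sqrt(dx^2 + dy^2)
  phi <- atan2(dx, -dy) * 180 / pi  # 0 = anterior (-y), +/-180 = posterior
  ring <- abs(r2d - lay$mand_radius) <= lay$mand_halfwidth & abs(phi) <= lay$mand_halfangle
  mand <- array(FALSE, dim = g$dims)
  zin <- zc >= lay$mand_z[1] & zc <= lay$mand_z[2]
  mand[, , zin] <- ring

  m <- lapply(specs, function(s) ellipsoid_mask(g, s$center, s$axes))
  # enforce pairwise disjointness: mandible > parotids > submandibulars
  m$PG_left <- m$PG_left & !mand
  m$PG_right <- m$PG_right & !mand
  pg_union <- m$PG_left | m$PG_right
  m$SMG_left <- m$SMG_left & !mand & !pg_union
  m$SMG_right <- m$SMG_right & !mand & !pg_union

  structure_set(
    PG_left = roi_mask("PG_left", g, m$PG_left),
    PG_right = roi_mask("PG_right", g, m$PG_right),
    SMG_left = roi_mask("SMG_left", g, m$SMG_left),
    SMG_right = roi_mask("SMG_right", g, m$SMG_right),
    mandible = roi_mask("mandible", g, mand),
    tumor_laterality = laterality
  )
}

#' Generate one patient's dose field
#'
#' An ipsilateral-skewed Gaussian kernel: the prescription dose at a target
#' point placed near the medial-inferior aspect of the ipsilateral parotid,
#' falling off isotropically with the (jittered) kernel width, plus additive
#' Gaussian noise truncated at three standard deviations and clipped at zero.
#' Ipsilateral structures therefore receive systematically higher dose than
#' contralateral ones.
#'
#' @param structures a `structure_set` (defines grid and laterality).
#' @param config a `cohort_config`.
#' @param patient_seed integer seed for this patient's dose draws.
#' @return A `dose_grid` with attributes `target_mm` and `sigma_mm`.
#' @export
generate_dose <- function(structures, config, patient_seed) {
  g <- structures$grid
  roles <- map_laterality(structures)
  cen <- mask_centroid(roles$iPG)
  medial <- if (roles$i_side == "left") -1 else 1

  with_local_seed(patient_seed, {
    tj <- config$target_jitter_mm
    target <- cen + c(medial * 20, 0, -15) + stats::runif(3, -tj, tj)
    # per-axis width jitter: anisotropic fall-off emulates plan-to-plan
    # variation in the dose gradient along each direction
    sigma <- config$dose_sigma_mm *
      (1 + stats::runif(3, -config$sigma_jitter_frac, config$sigma_jitter_frac))
    noise <- if (config$dose_noise_sd_cgy > 0) {
      nz <- stats::rnorm(prod(g$dims), 0, config$dose_noise_sd_cgy)
      lim <- 3 * config$dose_noise_sd_cgy
      pmin(pmax(nz, -lim), lim)
    } else 0
  })

  ex <- exp(-((axis_coords(g, 1) - target[1])^2) / (2 * sigma[1]^2))
  ey <- exp(-((axis_coords(g, 2) - target[2])^2) / (2 * sigma[2]^2))
  ez <- exp(-((axis_coords(g, 3) - target[3])^2) / (2 * sigma[3]^2))
  vals <- config$prescription_cgy * outer(outer(ex, ey), ez)
  vals <- pmax(vals + noise, 0)
  out <- dose_grid(g, array(vals, dim = g$dims))
  attr(out, "target_mm") <- target
  attr(out, "sigma_mm") <- sigma
  out
}

generate_clinical <- function(config, patient_seed, volumes_cc) {
  mix <- config$clinical_mix
  with_local_seed(patient_seed, {
    rec <- clinical_record(
      age_gt_65 = stats::rbinom(1, 1, mix$age_gt_65),
      gender = if (stats::rbinom(1, 1, mix$male) == 1) "male" else "female",
      race = sample(names(mix$race), 1, prob = mix$race),
      chemo = stats::rbinom(1, 1, mix$chemo),
      tumor_site = sample(names(mix$site), 1, prob = mix$site),
      volumes_cc = volumes_cc
    )
  })
  rec
}

# logistic outcome mechanism on scaled dose features + clinical terms
outcome_logit <- function(config, which, features, clinical_enc) {
  w <- config$effect_subvolumes[[which]]
  z <- unname(config$intercepts[which])
  if (length(w)) z <- z + sum(w * features[names(w)] / config$dose_scale_cgy)
  ce <- config$clinical_effects[[which]]
  if (length(ce)) z <- z + sum(ce * clinical_enc[names(ce)])
  z
}

# realize a timeline consistent with the drawn labels (monotone template)
generate_timeline <- function(config, patient_seed, pid, injury, recovery) {
  visits <- visit_schedule()
  with_local_seed(patient_seed, {
    if (injury == 0) {
      grades <- stats::rbinom(length(visits), 1, 0.35)  # symptomatic-or-not, never >= 2
    } else {
      onset <- as.integer(sample(names(config$onset_probs), 1,
                                 prob = config$onset_probs))
      peak <- 2L + stats::rbinom(1, 1, 0.2)
      grades <- integer(length(visits))
      grades[visits < onset] <- 1L
      if (recovery == 1) {
        rec_visit <- sample(visits[visits > 180L], 1)
        grades[visits >= onset & visits < rec_visit] <- peak
        grades[visits == rec_visit] <- 1L
        grades[visits > rec_visit] <- 0L
      } else {
        grades[visits == onset] <- peak
        grades[visits > onset] <- 2L
      }
    }
  })
  assessment_timeline(pid, visits, grades)
}

patient_seed_base <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1e6) * 2000 + i * 10) %% 2147483640)
}

#' Generate one synthetic patient
#'
#' Runs anatomy, dose, the geometric subvolume pipeline, clinical covariates,
#' the logistic outcome mechanism, and the timeline realization for patient
#' `i` of the configured cohort. Fully reproducible from (config seed, i).
#'
#' @param config a `cohort_config`.
#' @param i patient index (1-based).
#' @param keep_volumes keep the voxel data (structure set, dose, subvolumes)
#'   on the returned object; off by default to bound memory for large
#'   cohorts.
#' @return An object of class `synthetic_patient`.
#' @export
generate_patient <- function(config, i, keep_volumes = FALSE) {
  base <- patient_seed_base(config$seed, i)
  structures <- generate_anatomy(config, base + 1L)
  dose <- generate_dose(structures, config, base + 2L)
  subvols <- derive_subvolumes(structures, margin_mm = 3)
  feats <- extract_dose_features(subvols, dose)
  vols <- c(iPG = mask_volume_cc(subvols$expanded$iPG),
            cPG = mask_volume_cc(subvols$expanded$cPG),
            iSMG = mask_volume_cc(subvols$expanded$iSMG),
            cSMG = mask_volume_cc(subvols$expanded$cSMG),
            iOC = mask_volume_cc(subvols$masks$iOC),
            cOC = mask_volume_cc(subvols$masks$cOC))
  clin <- generate_clinical(config, base + 3L, vols)
  enc <- encode_clinical(clin)

  with_local_seed(base + 4L, {
    injury <- as.numeric(
      stats::rbinom(1, 1, stats::plogis(outcome_logit(config, "injury", feats, enc))))
    recovery <- if (injury == 1)
      as.numeric(stats::rbinom(1, 1, stats::plogis(outcome_logit(config, "recovery", feats, enc))))
    else NA_real_
  })
  pid <- sprintf("P%04d", i)
  timeline <- generate_timeline(config, base + 5L, pid, injury,
                                if (is.na(recovery)) 0 else recovery)
  structure(list(
    patient_id = pid,
    structure_set = if (keep_volumes) structures else NULL,
    dose = if (keep_volumes) dose else NULL,
    subvolumes = if (keep_volumes) subvols else NULL,
    features = feats, clinical = clin, timeline = timeline,
    latent = list(injury = injury, recovery = recovery),
    tumor_laterality = structures$tumor_laterality
  ), class = "synthetic_patient")
}

#' Generate a synthetic cohort
#'
#' @param config a `cohort_config`.
#' @param keep_volumes keep per-patient voxel data (memory-heavy; default off).
#' @return An object of class `synthetic_cohort`: list of
#'   `synthetic_patient`s with the config attached.
#' @export
generate_cohort <- function(config, keep_volumes = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(config, i, keep_volumes = keep_volumes))
  structure(list(patients = patients, config = config), class = "synthetic_cohort")
}

#' Assemble the feature table of a synthetic cohort
#'
#' Outcome labels are derived from the realized timelines (which reproduce
#' the latent labels by construction — a tested round-trip property).
#'
#' @param cohort a `synthetic_cohort`.
#' @return A `feature_table`.
#' @export
cohort_feature_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  labs <- lapply(cohort$patients, function(p) derive_outcomes(p$timeline))
  build_design_matrix(
    patient_ids = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    dose_features = lapply(cohort$patients, `[[`, "features"),
    clinical = lapply(cohort$patients, `[[`, "clinical"),
    injury = vapply(labs, `[[`, numeric(1), "injury"),
    recovery = vapply(labs, `[[`, numeric(1), "recovery")
  )
}

#' Subvolumes carrying a planted effect
#'
#' @param config a `cohort_config`.
#' @param which `"injury"` or `"recovery"`.
#' @return Character vector of subvolume names named in the effect weights.
#' @export
planted_subvolumes <- function(config, which = c("injury", "recovery")) {
  which <- match.arg(which)
  unique(sub("_D[0-9]+$", "", names(config$effect_subvolumes[[which]])))
}
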