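#' Validate a pipeline run configuration
#'
#' The run configuration binds every stage parameter: cohort size and seed,
#' geometry margin, permutation count, fold counts, iteration count, penalty
#' grid, and the output directory. Unknown fields are rejected so typos fail
#' fast; all randomness flows from the single `seed`.
#'
#' @param config a named list, or a path to a JSON file holding one.
#' @return The validated config (class `run_config`) with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  defaults <- list(
    n_patients = 30L, seed = 1L, out_dir = NULL, margin_mm = 3,
    n_perm = 1000L, outer_folds = 5L, inner_folds = 5L, n_iterations = 50L,
    lambda_grid = default_lambda_grid(), make_figures = TRUE,
    cohort = list()   # overrides forwarded to cohort_config()
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("run_config requires out_dir")
  stopifnot(cfg$n_patients >= 1, cfg$margin_mm >= 0, cfg$n_perm >= 1,
            cfg$outer_folds >= 2, cfg$inner_folds >= 2, cfg$n_iterations >= 1,
            length(cfg$lambda_grid) >= 1)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

# a stage is up to date when all outputs exist and the recorded input hashes
# match the current ones
stage_current <- function(record, inputs, outputs) {
  if (is.null(record)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  cur <- hash_files(inputs[file.exists(inputs)])
  old <- unlist(record$inputs)
  length(cur) == length(old) && all(names(cur) %in% names(old)) &&
    all(old[names(cur)] == cur)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> segment -> features -> permtest -> fit -> report into
#' `config$out_dir`. Each stage is idempotent: on rerun a stage is skipped
#' when its outputs exist and its recorded input hashes are unchanged, so
#' deleting an intermediate regenerates that stage and anything downstream of
#' a changed file, never the upstream stages. A run manifest (software
#' version, config hash, per-stage input/output hashes, timings, warnings)
#' is written last.
#'
#' @param config a `run_config` (or list / JSON path accepted by
#'   [run_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vol_dir <- file.path(out, "volumes")
  seg_dir <- file.path(out, "subvolumes")
  manifest_path <- file.path(out, "run_manifest.json")
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else NULL
  prev_stages <- prev$stages
  manifest <- list(
    software = paste0("xerosubvol ", as.character(utils::packageVersion("xerosubvol"))),
    config_hash = config_hash(cfg),
    settings_log = list(
      dvh_quantile_convention = "linear interpolation of descending sample at rank x/100*(N-1), 0-based",
      sector_frame = "whole-gland centroid, single angular frame, boundaries at +/-60 deg about the medial vector",
      si_cut_tie = "cut-plane voxel centers assigned inferior",
      injury_window_days = 183, recovery_window_days = 548,
      threshold_rule = "Youden J on pooled outer-test scores"
    ),
    stages = list(), warnings = list()
  )

  run_stage <- function(name, inputs, outputs, fun) {
    rec <- prev_stages[[name]]
    if (stage_current(rec, inputs, outputs)) {
      rec$ran <- FALSE
      manifest$stages[[name]] <<- rec
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    warns <- character(0)
    withCallingHandlers(fun(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      ran = TRUE,
      inputs = as.list(hash_files(inputs[file.exists(inputs)])),
      outputs = as.list(hash_files(outputs[file.exists(outputs)])),
      elapsed_sec = round(proc.time()[3] - t0, 2),
      warnings = warns
    )
    if (length(warns)) manifest$warnings[[name]] <<- warns
    invisible(NULL)
  }

  ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  clinical_csv <- file.path(out, "clinical.csv")
  assessments_csv <- file.path(out, "assessments.csv")
  truth_csv <- file.path(out, "truth.csv")
  features_csv <- file.path(out, "features.csv")
  organ_files <- as.vector(t(outer(ids, c("PG_left", "PG_right", "SMG_left",
                                          "SMG_right", "mandible", "dose"),
                                   function(a, b) file.path(vol_dir, paste0(a, "_", b, ".nii.gz")))))
  subvol_files <- as.vector(t(outer(ids, subvolume_names(),
                                    function(a, b) file.path(seg_dir, paste0(a, "_", b, ".nii.gz")))))
  seg_manifest <- file.path(out, "subvolumes.json")

  ## 1. simulate ------------------------------------------------------------
  run_stage("simulate", inputs = character(0),
            outputs = c(organ_files, clinical_csv, assessments_csv, truth_csv),
            fun = function() {
    dir.create(vol_dir, showWarnings = FALSE)
    ccfg <- do.call(cohort_config,
                    c(list(n_patients = cfg$n_patients, seed = cfg$seed), cfg$cohort))
    clin <- list(); assess <- list(); truth <- list()
    for (i in seq_len(cfg$n_patients)) {
      p <- generate_patient(ccfg, i, keep_volumes = TRUE)
      for (roi in c("PG_left", "PG_right", "SMG_left", "SMG_right", "mandible"))
        write_volume(p$structure_set[[roi]],
                     file.path(vol_dir, paste0(p$patient_id, "_", roi, ".nii.gz")))
      write_volume(p$dose, file.path(vol_dir, paste0(p$patient_id, "_dose.nii.gz")))
      r <- p$clinical
      clin[[i]] <- data.frame(patient_id = p$patient_id,
                              tumor_laterality = p$tumor_laterality,
                              age_gt_65 = r$age_gt_65, gender = r$gender,
                              race = r$race, chemo = r$chemo,
                              tumor_site = r$tumor_site,
                              t(r$volumes_cc), stringsAsFactors = FALSE)
      assess[[i]] <- data.frame(patient_id = p$patient_id,
                                days_post_rt = p$timeline$days_post_rt,
                                ctcae_grade = p$timeline$ctcae_grade)
      truth[[i]] <- data.frame(patient_id = p$patient_id,
                               injury = p$latent$injury, recovery = p$latent$recovery)
    }
    write_table_units(do.call(rbind, clin), clinical_csv,
                      "volumes iPG..cOC: cc; age_gt_65/chemo: 0/1")
    write_table_units(do.call(rbind, assess), assessments_csv,
                      "days_post_rt: days; ctcae_grade: CTCAE 0-3")
    write_table_units(do.call(rbind, truth), truth_csv, "labels: 0/1")
  })

  ## 2. segment -------------------------------------------------------------
  run_stage("segment", inputs = c(organ_files, clinical_csv),
            outputs = c(subvol_files, seg_manifest),
            fun = function() {
    dir.create(seg_dir, showWarnings = FALSE)
    clin <- read_table_units(clinical_csv)
    man <- list()
    for (pid in ids) {
      rd <- function(roi) load_volume(file.path(vol_dir, paste0(pid, "_", roi, ".nii.gz")),
                                      "mask", roi_name = roi)
      ss <- structure_set(rd("PG_left"), rd("PG_right"), rd("SMG_left"),
                          rd("SMG_right"), rd("mandible"),
                          clin$tumor_laterality[clin$patient_id == pid])
      sv <- derive_subvolumes(ss, margin_mm = cfg$margin_mm)
      for (nm in subvolume_names()) {
        write_volume(sv$masks[[nm]], file.path(seg_dir, paste0(pid, "_", nm, ".nii.gz")))
        man[[length(man) + 1L]] <- list(patient_id = pid, subvolume = nm,
                                        n_voxels = sum(sv$masks[[nm]]$voxels),
                                        volume_cc = mask_volume_cc(sv$masks[[nm]]))
      }
    }
    jsonlite::write_json(man, seg_manifest, auto_unbox = TRUE, digits = NA)
  })

  ## 3. features ------------------------------------------------------------
  run_stage("features", inputs = c(subvol_files, organ_files, clinical_csv,
                                   assessments_csv, seg_manifest),
            outputs = features_csv,
            fun = function() {
    clin <- read_table_units(clinical_csv)
    assess <- read_table_units(assessments_csv)
    feats <- list(); recs <- list(); inj <- numeric(length(ids)); rec <- numeric(length(ids))
    for (k in seq_along(ids)) {
      pid <- ids[k]
      dose <- load_volume(file.path(vol_dir, paste0(pid, "_dose.nii.gz")), "dose")
      masks <- lapply(subvolume_names(), function(nm)
        load_volume(file.path(seg_dir, paste0(pid, "_", nm, ".nii.gz")), "mask",
                    roi_name = nm, grid = dose$grid))
      names(masks) <- subvolume_names()
      sv <- structure(list(masks = masks, grid = dose$grid, margin_mm = cfg$margin_mm),
                      class = "subvolume_set")
      feats[[k]] <- extract_dose_features(sv, dose)
      cr <- clin[clin$patient_id == pid, ]
      recs[[k]] <- clinical_record(cr$age_gt_65, cr$gender, cr$race, cr$chemo,
                                   cr$tumor_site,
                                   c(iPG = cr$iPG, cPG = cr$cPG, iSMG = cr$iSMG,
                                     cSMG = cr$cSMG, iOC = cr$iOC, cOC = cr$cOC))
      a <- assess[assess$patient_id == pid, ]
      lab <- derive_outcomes(assessment_timeline(pid, a$days_post_rt, a$ctcae_grade))
      inj[k] <- lab$injury; rec[k] <- lab$recovery
    }
    tab <- build_design_matrix(ids, feats, recs, inj, rec)
    write_table_units(tab, features_csv,
                      "dose features: cGy; vol_*: cc; labels/dummies: 0/1")
  })

  ## 4. permtest ------------------------------------------------------------
  perm_files <- file.path(out, c("permtest_injury.csv", "permtest_recovery.csv"))
  run_stage("permtest", inputs = features_csv, outputs = perm_files,
            fun = function() {
    tab <- read_feature_table(features_csv)
    for (oc in c("injury", "recovery")) {
      pop <- model_population(tab, oc)
      dir <- if (oc == "injury") "greater" else "less"
      pr <- maxT_permutation_test(pop$X[, dose_feature_names()], pop$y,
                                  n_perm = cfg$n_perm, direction = dir,
                                  seed = cfg$seed + 1L)
      write_table_units(as.data.frame(pr), file.path(out, paste0("permtest_", oc, ".csv")),
                        "T: normalized mean-difference statistic; p: permutation-adjusted")
    }
  })

  ## 5. fit -----------------------------------------------------------------
  report_json <- file.path(out, "model_report.json")
  run_stage("fit", inputs = features_csv, outputs = report_json,
            fun = function() {
    tab <- read_feature_table(features_csv)
    rep <- list()
    for (oc in c("injury", "recovery")) {
      ev <- nested_cv_evaluate(tab, oc, outer_folds = cfg$outer_folds,
                               inner_folds = cfg$inner_folds,
                               lambda_grid = cfg$lambda_grid,
                               n_iterations = cfg$n_iterations,
                               seed = cfg$seed + 2L)
      rep[[oc]] <- list(auc = ev$auc_mean, auc_sd = ev$auc_sd,
                        sensitivity = ev$sensitivity_mean, sensitivity_sd = ev$sensitivity_sd,
                        specificity = ev$specificity_mean, specificity_sd = ev$specificity_sd,
                        n_iterations = ev$n_iterations, lambda_modal = ev$lambda_modal,
                        importance = as.list(ev$importance))
    }
    jsonlite::write_json(rep, report_json, auto_unbox = TRUE, digits = NA)
  })

  ## 6. report --------------------------------------------------------------
  report_files <- file.path(out, c("report_group_summaries.csv",
                                   "report_prevalence.csv", "report_importance.csv"))
  run_stage("report", inputs = c(features_csv, assessments_csv, perm_files, report_json),
            outputs = report_files,
            fun = function() {
    tab <- read_feature_table(features_csv)
    write_table_units(group_summaries(tab), report_files[1],
                      "mean: cGy; cv: dimensionless (sd/mean)")
    assess <- read_table_units(assessments_csv)
    tls <- lapply(split(assess, assess$patient_id), function(a)
      assessment_timeline(a$patient_id[1], a$days_post_rt, a$ctcae_grade))
    write_table_units(prevalence_curve(tls), report_files[2],
                      "lo/hi: days post-RT; prevalence: proportion")
    rep <- jsonlite::read_json(report_json, simplifyVector = TRUE)
    imp <- data.frame(feature = dose_feature_names(),
                      importance_injury = unlist(rep$injury$importance)[dose_feature_names()],
                      importance_recovery = unlist(rep$recovery$importance)[dose_feature_names()],
                      stringsAsFactors = FALSE)
    for (oc in c("injury", "recovery")) {
      pr <- read_table_units(file.path(out, paste0("permtest_", oc, ".csv")))
      imp[[paste0("significant_", oc)]] <- pr$significant[match(imp$feature, pr$feature)]
    }
    write_table_units(imp, report_files[3],
                      "importance: normalized to [-100, 100]; significant: logical")
    if (isTRUE(cfg$make_figures)) render_importance_figure(imp, file.path(out, "report_maps.png"))
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a features CSV back as a `feature_table`
#' @param path the features CSV written by the pipeline.
#' @export
read_feature_table <- function(path) {
  raw <- read_table_units(path)
  build_design_matrix(raw$patient_id, as.matrix(raw[, dose_feature_names()]),
                      as.matrix(raw[, clinical_feature_names()]),
                      raw$injury, raw$recovery)
}

# simple heat-map panels of the importance/significance maps (one row per
# subvolume, one column per Dx); diagnostic output, not publication styling
render_importance_figure <- function(imp, path) {
  sv <- subvolume_names(); xs <- seq(10, 90, 10)
  as_mat <- function(col) {
    m <- matrix(imp[[col]][match(as.vector(t(outer(sv, xs, function(a, b)
      paste0(a, "_D", b)))), imp$feature)], nrow = length(sv), byrow = TRUE)
    dimnames(m) <- list(sv, paste0("D", xs)); m
  }
  grDevices::png(path, width = 1200, height = 700)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 8, 3, 1))
  for (oc in c("injury", "recovery")) {
    m <- as_mat(paste0("importance_", oc))
    graphics::image(x = xs, y = seq_along(sv), z = t(m[rev(seq_along(sv)), ]),
                    zlim = c(-100, 100),
                    col = grDevices::hcl.colors(41, "Blue-Red 2"),
                    xlab = "Dx", ylab = "", yaxt = "n",
                    main = paste0(oc, " importance [-100, 100]"))
    graphics::axis(2, at = seq_along(sv), labels = rev(sv), las = 2, cex.axis = 0.6)
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
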