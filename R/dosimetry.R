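#' Cumulative dose-volume histogram of a subvolume
#'
#' Collects the dose at every voxel of the mask and sorts it in descending
#' order. No dose binning is applied: the curve is the exact empirical
#' distribution, so downstream Dx values carry no binning tolerance.
#'
#' @param mask a nonempty `roi_mask`.
#' @param dose a `dose_grid` on the same voxel grid.
#' @return An object of class `dvh_curve`: list with `subvolume`, `sample`
#'   (descending voxel doses, cGy) and `n_voxels`.
#' @export
cumulative_dvh <- function(mask, dose) {
  stopifnot(inherits(mask, "roi_mask"), inherits(dose, "dose_grid"))
  stop_if_grid_mismatch(mask$grid, dose$grid, "mask and dose")
  if (!any(mask$voxels)) stop(sprintf("mask '%s' is empty; no DVH", mask$roi_name))
  s <- sort(dose$values[mask$voxels], decreasing = TRUE)
  structure(list(subvolume = mask$roi_name, sample = s, n_voxels = length(s)),
            class = "dvh_curve")
}

#' Dose covering x percent of a subvolume (Dx)
#'
#' Dx is the dose received by the hottest x% of the structure's volume. It is
#' computed by linear interpolation of the descending empirical quantile
#' function at rank position `x/100 * (N - 1)` (0-based) over the sorted
#' voxel sample. Several interpolation conventions exist and differ on small
#' subvolumes; this one is fixed and documented in every report.
#'
#' @param dvh a `dvh_curve`.
#' @param x_percent volume percentage, strictly between 0 and 100.
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(dvh, x_percent) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (!is.finite(x_percent) || x_percent <= 0 || x_percent >= 100)
    stop("x_percent must lie strictly between 0 and 100")
  s <- dvh$sample
  n <- length(s)
  if (n == 1L) return(s[1])
  r <- x_percent / 100 * (n - 1)           # 0-based fractional rank
  lo <- floor(r)
  frac <- r - lo
  if (lo + 2 > n) return(s[n])
  s[lo + 1] * (1 - frac) + s[lo + 2] * frac
}

#' Extract the 198 D10-D90 dose features of a patient
#'
#' For each of the 22 subvolumes, computes D10 through D90 in 10% increments
#' (9 per subvolume, 198 in total). Column order is deterministic: subvolume
#' names in lexical order, then x ascending; names are `<subvolume>_D<x>`.
#' An empty subvolume (possible on degenerate geometry) contributes zeros
#' with a warning.
#'
#' @param subvols a `subvolume_set`.
#' @param dose a `dose_grid` on the same grid.
#' @return Named numeric vector of length 198, cGy.
#' @export
extract_dose_features <- function(subvols, dose) {
  stopifnot(inherits(subvols, "subvolume_set"), inherits(dose, "dose_grid"))
  stop_if_grid_mismatch(subvols$grid, dose$grid, "subvolumes and dose")
  xs <- seq(10, 90, by = 10)
  nms <- as.vector(t(outer(subvolume_names(), xs,
                           function(a, b) paste0(a, "_D", b))))
  out <- stats::setNames(numeric(length(nms)), nms)
  for (sv in subvolume_names()) {
    m <- subvols$masks[[sv]]
    if (is.null(m)) stop(sprintf("subvolume '%s' missing", sv))
    if (!any(m$voxels)) {
      warning(sprintf("subvolume '%s' is empty; its dose features are set to 0", sv))
      next
    }
    dvh <- cumulative_dvh(m, dose)
    for (x in xs) out[paste0(sv, "_D", x)] <- dose_at_volume(dvh, x)
  }
  out
}

#' Per-patient clinical record
#'
#' @param age_gt_65 0/1, age above 65 years at start of radiotherapy.
#' @param gender `"male"` or `"female"`.
#' @param race `"white"`, `"african_american"` or `"other"`.
#' @param chemo 0/1, ever received chemotherapy.
#' @param tumor_site one of `"nasopharynx"`, `"oral_cavity"`, `"oropharynx"`,
#'   `"hypopharynx"`, `"larynx"`, `"others"`.
#' @param volumes_cc named numeric vector with entries `iPG`, `cPG`, `iSMG`,
#'   `cSMG`, `iOC`, `cOC` — pre-treatment structure volumes in cc (expanded
#'   contours).
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(age_gt_65, gender, race, chemo, tumor_site, volumes_cc) {
  if (!gender %in% c("male", "female")) stop("unknown gender category: ", gender)
  if (!race %in% c("white", "african_american", "other"))
    stop("unknown race category: ", race)
  sites <- c("nasopharynx", "oral_cavity", "oropharynx", "hypopharynx", "larynx", "others")
  if (!tumor_site %in% sites) stop("unknown tumor site: ", tumor_site)
  if (!all(age_gt_65 %in% c(0, 1)) || !all(chemo %in% c(0, 1)))
    stop("age_gt_65 and chemo must be 0/1")
  need <- c("iPG", "cPG", "iSMG", "cSMG", "iOC", "cOC")
  if (!all(need %in% names(volumes_cc))) stop("volumes_cc must name all six structures")
  if (any(volumes_cc[need] < 0)) stop("volumes must be nonnegative")
  structure(list(age_gt_65 = as.numeric(age_gt_65), gender = gender, race = race,
                 chemo = as.numeric(chemo), tumor_site = tumor_site,
                 volumes_cc = volumes_cc[need]),
            class = "clinical_record")
}

#' Encode a clinical record as the 16 model columns
#'
#' Dummy coding with `white` as the race reference and `others` as the
#' tumor-site reference: age>65 (1), male (1), race (2), chemotherapy (1),
#' tumor site (5), six structure volumes in cc (6) — 16 columns, so together
#' with the 198 dose features the design matrix has 214 predictors.
#'
#' @param rec a `clinical_record`.
#' @return Named numeric vector of length 16.
#' @export
encode_clinical <- function(rec) {
  stopifnot(inherits(rec, "clinical_record"))
  c(age_gt_65 = rec$age_gt_65,
    male = as.numeric(rec$gender == "male"),
    race_african_american = as.numeric(rec$race == "african_american"),
    race_other = as.numeric(rec$race == "other"),
    chemo = rec$chemo,
    site_nasopharynx = as.numeric(rec$tumor_site == "nasopharynx"),
    site_oral_cavity = as.numeric(rec$tumor_site == "oral_cavity"),
    site_oropharynx = as.numeric(rec$tumor_site == "oropharynx"),
    site_hypopharynx = as.numeric(rec$tumor_site == "hypopharynx"),
    site_larynx = as.numeric(rec$tumor_site == "larynx"),
    vol_iPG = unname(rec$volumes_cc["iPG"]),
    vol_cPG = unname(rec$volumes_cc["cPG"]),
    vol_iSMG = unname(rec$volumes_cc["iSMG"]),
    vol_cSMG = unname(rec$volumes_cc["cSMG"]),
    vol_iOC = unname(rec$volumes_cc["iOC"]),
    vol_cOC = unname(rec$volumes_cc["cOC"]))
}

#' Names of the 198 dose-feature columns (canonical order)
#' @export
dose_feature_names <- function() {
  as.vector(t(outer(subvolume_names(), seq(10, 90, by = 10),
                    function(a, b) paste0(a, "_D", b))))
}

#' Names of the 16 encoded clinical columns
#' @export
clinical_feature_names <- function() {
  c("age_gt_65", "male", "race_african_american", "race_other", "chemo",
    "site_nasopharynx", "site_oral_cavity", "site_oropharynx",
    "site_hypopharynx", "site_larynx",
    "vol_iPG", "vol_cPG", "vol_iSMG", "vol_cSMG", "vol_iOC", "vol_cOC")
}

#' Assemble the cohort design matrix
#'
#' Joins the 198 dose features and 16 encoded clinical columns per patient
#' and attaches the outcome labels. The injury label is defined for every
#' patient; the recovery label only for injured patients (the recovery model
#' population), and is `NA` otherwise.
#'
#' @param patient_ids character vector, unique, one per patient.
#' @param dose_features numeric matrix (n x 198) or list of named vectors as
#'   returned by [extract_dose_features()].
#' @param clinical list of `clinical_record`s (or an n x 16 numeric matrix of
#'   already-encoded columns).
#' @param injury 0/1 vector.
#' @param recovery 0/1 vector, `NA` where `injury == 0`.
#' @return An object of class `feature_table`: a data.frame with columns
#'   `patient_id`, the 214 predictors, `injury`, `recovery`.
#' @export
build_design_matrix <- function(patient_ids, dose_features, clinical, injury, recovery) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("duplicated patient ids")
  if (any(is.na(patient_ids))) stop("missing patient ids")
  if (is.list(dose_features) && !is.data.frame(dose_features))
    dose_features <- do.call(rbind, dose_features)
  dose_features <- as.matrix(dose_features)
  if (nrow(dose_features) != n || ncol(dose_features) != 198L)
    stop("dose_features must be n x 198")
  dose_features <- dose_features[, dose_feature_names(), drop = FALSE]
  if (is.list(clinical) && !is.data.frame(clinical))
    clinical <- do.call(rbind, lapply(clinical, encode_clinical))
  clinical <- as.matrix(clinical)
  if (nrow(clinical) != n || ncol(clinical) != 16L)
    stop("clinical must encode to n x 16")
  clinical <- clinical[, clinical_feature_names(), drop = FALSE]
  if (length(injury) != n || length(recovery) != n)
    stop("outcome labels must match the number of patients")
  if (any(is.na(injury))) stop("injury label missing for some patients")
  if (any(injury == 0 & !is.na(recovery)))
    stop("recovery must be undefined (NA) for non-injured patients")
  if (any(injury == 1 & is.na(recovery)))
    stop("recovery label missing for some injured patients")
  out <- data.frame(patient_id = as.character(patient_ids),
                    dose_features, clinical,
                    injury = as.numeric(injury), recovery = as.numeric(recovery),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(out[, c(dose_feature_names(), clinical_feature_names())]))
    stop("missing values in predictors after encoding")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Predictor matrix and labels for one outcome model
#'
#' The injury model uses all patients; the recovery model is restricted to
#' the injured subset.
#'
#' @param table a `feature_table`.
#' @param outcome `"injury"` or `"recovery"`.
#' @return List with `X` (numeric matrix, 214 columns), `y` (0/1), `ids`.
#' @export
model_population <- function(table, outcome = c("injury", "recovery")) {
  outcome <- match.arg(outcome)
  rows <- if (outcome == "injury") rep(TRUE, nrow(table)) else table$injury == 1
  cols <- c(dose_feature_names(), clinical_feature_names())
  list(X = as.matrix(table[rows, cols, drop = FALSE]),
       y = as.numeric(table[[outcome]][rows]),
       ids = table$patient_id[rows])
}

#' Read a deposited feature table from CSV
#'
#' Maps the columns of an externally deposited per-patient feature CSV onto
#' the package's `feature_table` schema. Column-name matching is
#' case-insensitive; the file must provide a patient id, the 198 dose
#' features, the 16 clinical columns, and the injury/recovery labels.
#'
#' @param path CSV file path.
#' @return A `feature_table`.
#' @export
read_deposited_features <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- c("patient_id", dose_feature_names(), clinical_feature_names(),
            "injury", "recovery")
  pos <- match(tolower(want), tolower(names(raw)))
  if (anyNA(pos)) {
    miss <- want[is.na(pos)]
    stop(sprintf("deposited table lacks %d required columns (first missing: %s)",
                 length(miss), miss[1]))
  }
  raw <- raw[, pos]
  names(raw) <- want
  build_design_matrix(raw$patient_id,
                      as.matrix(raw[, dose_feature_names()]),
                      as.matrix(raw[, clinical_feature_names()]),
                      raw$injury, raw$recovery)
}
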