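# Study-style screening for type 2 diabetes cohorts: ADA diagnostic
# criteria, cardiovascular risk-factor count, exclusion rules, and UKPDS
# 10-year fatal-CHD risk tiering.  All functions are vectorized over the
# rows of a clinical table; a criterion whose inputs are missing counts
# as not met (and is reported), mirroring the handling of incomplete
# records in screening studies.

#' Columns of a clinical record table
#'
#' @return Character vector naming the columns the eligibility and
#'   stratification functions understand.
#' @export
clinical_columns <- function() {
  c("patient_id", "age", "sex", "dm_status", "dm_duration", "hba1c",
    "fbg", "post_challenge_glucose", "on_hypoglycemic_treatment",
    "sbp", "dbp", "on_antihypertensive", "total_cholesterol", "hdl",
    "triglycerides", "on_lipid_lowering", "current_smoker", "bmi",
    "regular_exercise", "family_history_mi", "prior_chd_or_symptoms",
    "abnormal_ecg", "prior_mi_cabg_stent", "ukpds_fatal_risk_pct")
}

miss <- function(x, default = NA) if (is.null(x)) default else x

#' Does a record meet the T2DM diagnostic criteria?
#'
#' ADA-style diagnosis: HbA1c >= 6.5%, fasting blood glucose >= 7.0
#' mmol/L, post-challenge (2 h, 75 g OGTT) glucose >= 11.1 mmol/L, or
#' current use of hypoglycemic treatment.  Missing labs count as not
#' met; a row with all four inputs missing is an error.
#'
#' @param records a data frame with (any of) columns `hba1c`, `fbg`,
#'   `post_challenge_glucose`, `on_hypoglycemic_treatment`.
#' @return Logical vector, one element per row.
#' @examples
#' meets_t2dm_criteria(data.frame(hba1c = c(8.7, 6.4),
#'                                fbg = c(NA, 6.9),
#'                                on_hypoglycemic_treatment = FALSE))
#' @export
meets_t2dm_criteria <- function(records) {
  stopifnot(is.data.frame(records))
  hba1c <- miss(records$hba1c)
  fbg <- miss(records$fbg)
  ogtt <- miss(records$post_challenge_glucose)
  trt <- miss(records$on_hypoglycemic_treatment)
  n <- nrow(records)
  all_missing <- rowSums(cbind(!is.na(rep_len(hba1c, n)),
                               !is.na(rep_len(fbg, n)),
                               !is.na(rep_len(ogtt, n)),
                               !is.na(rep_len(trt, n)))) == 0
  if (any(all_missing)) {
    stop(sprintf(
      "row(s) %s: no diabetes lab or treatment information available",
      paste(which(all_missing), collapse = ", ")), call. = FALSE)
  }
  isTRUE_vec(hba1c >= 6.5, n) | isTRUE_vec(fbg >= 7.0, n) |
    isTRUE_vec(ogtt >= 11.1, n) | isTRUE_vec(trt, n)
}

# elementwise "TRUE and not NA"
isTRUE_vec <- function(x, n) {
  x <- rep_len(x, n)
  !is.na(x) & x
}

#' Count cardiovascular risk factors
#'
#' Counts up to five factors: hypertension (SBP >= 140 or DBP >= 90 mmHg
#' or antihypertensive medication), dyslipidemia (total cholesterol >=
#' 5.2 mmol/L or lipid-lowering treatment), current smoking, obesity or
#' lack of exercise (BMI >= 28 kg/m2 or not exercising regularly at
#' least three times a week), and family history of myocardial
#' infarction in first-degree relatives.  A factor whose inputs are all
#' missing counts as not met and is flagged in the `missing` attribute.
#'
#' @param records a clinical data frame (see [clinical_columns()]).
#' @return Integer vector in 0..5, with attribute `missing`: a logical
#'   matrix (rows x factors) marking criteria that could not be assessed.
#' @export
count_risk_factors <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  sbp <- rep_len(miss(records$sbp), n)
  dbp <- rep_len(miss(records$dbp), n)
  aht <- rep_len(miss(records$on_antihypertensive), n)
  tc <- rep_len(miss(records$total_cholesterol), n)
  llt <- rep_len(miss(records$on_lipid_lowering), n)
  smk <- rep_len(miss(records$current_smoker), n)
  bmi <- rep_len(miss(records$bmi), n)
  exr <- rep_len(miss(records$regular_exercise), n)
  fam <- rep_len(miss(records$family_history_mi), n)

  hyp <- isTRUE_vec(sbp >= 140, n) | isTRUE_vec(dbp >= 90, n) |
    isTRUE_vec(aht, n)
  dys <- isTRUE_vec(tc >= 5.2, n) | isTRUE_vec(llt, n)
  smoking <- isTRUE_vec(smk, n)
  obes <- isTRUE_vec(bmi >= 28, n) | isTRUE_vec(!exr, n)
  famhx <- isTRUE_vec(fam, n)

  missing <- cbind(
    hypertension = is.na(sbp) & is.na(dbp) & is.na(aht),
    dyslipidemia = is.na(tc) & is.na(llt),
    smoking = is.na(smk),
    obesity_or_inactivity = is.na(bmi) & is.na(exr),
    family_history = is.na(fam)
  )
  out <- as.integer(hyp + dys + smoking + obes + famhx)
  attr(out, "missing") <- missing
  out
}

#' Eligibility of a diabetes-cohort record
#'
#' A record is eligible when it meets the T2DM diagnostic criteria, has
#' at least one additional cardiovascular risk factor, and triggers none
#' of the exclusion rules: known or suspected CHD (or CHD symptoms),
#' abnormal resting ECG, prior myocardial infarction / CABG / stenting,
#' or incomplete data for any risk-factor criterion.
#'
#' @param records a clinical data frame.
#' @return A data frame with columns `eligible` (logical) and `reasons`
#'   (character; semicolon-separated failed rules, empty when eligible).
#' @export
is_eligible_dm <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  t2dm <- meets_t2dm_criteria(records)
  rf <- count_risk_factors(records)
  rf_missing <- attr(rf, "missing")
  chd <- isTRUE_vec(miss(records$prior_chd_or_symptoms, FALSE), n)
  ecg <- isTRUE_vec(miss(records$abnormal_ecg, FALSE), n)
  revasc <- isTRUE_vec(miss(records$prior_mi_cabg_stent, FALSE), n)
  incomplete <- rowSums(rf_missing) > 0

  reasons <- vapply(seq_len(n), function(i) {
    r <- character()
    if (!t2dm[i]) r <- c(r, "not_t2dm")
    if (rf[i] < 1) r <- c(r, "no_risk_factor")
    if (chd[i]) r <- c(r, "prior_chd_or_symptoms")
    if (ecg[i]) r <- c(r, "abnormal_ecg")
    if (revasc[i]) r <- c(r, "prior_mi_cabg_stent")
    if (incomplete[i]) {
      r <- c(r, paste0("incomplete_data:",
                       paste(colnames(rf_missing)[rf_missing[i, ]],
                             collapse = ",")))
    }
    paste(r, collapse = "; ")
  }, character(1))
  data.frame(eligible = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Assign a UKPDS fatal-risk tier
#'
#' Maps a precomputed UKPDS 10-year fatal-CHD risk percentage to the
#' study tiers: low (< 7.5%), moderate (7.5-15%, both boundaries
#' inclusive), high (> 15%).  The UKPDS risk engine itself is external:
#' its output percentage is an input column here, and any user-supplied
#' risk function can be plugged in upstream.
#'
#' @param ukpds_fatal_risk_pct numeric vector of risk percentages in
#'   \[0, 100\].
#' @param config a [ccta_config()] carrying the tier boundaries.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @examples
#' stratify_risk(c(7.4, 7.5, 15, 15.01))
#' @export
stratify_risk <- function(ukpds_fatal_risk_pct, config = ccta_config()) {
  x <- ukpds_fatal_risk_pct
  if (any(is.na(x) | x < 0 | x > 100)) {
    stop("ukpds_fatal_risk_pct must lie in [0, 100]", call. = FALSE)
  }
  tier <- ifelse(x < config$tier_low_max, "low",
                 ifelse(x <= config$tier_moderate_max, "moderate", "high"))
  factor(tier, levels = c("low", "moderate", "high"))
}
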