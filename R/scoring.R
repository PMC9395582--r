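# Per-patient plaque burden scores.  All five scores are deterministic
# functions of the lesion set: SIS counts diseased segments, SSS sums a
# 0-3 per-segment stenosis grade, SC = SSS/SIS (0 when SIS is 0), SPP
# flags a severe plaque in the left main or a proximal LAD/LCx/RCA
# segment, and CT-LeSc sums localization weight x composition factor x
# stenosis factor over lesions.

.spp_segments <- c("left_main", "lad_proximal", "lcx_proximal",
                   "rca_proximal")

check_patient <- function(p) {
  v <- validate_patient(p)
  if (length(v)) {
    stop(sprintf("patient '%s' fails validation:\n  %s",
                 p$patient_id, paste(v, collapse = "\n  ")), call. = FALSE)
  }
  invisible(p)
}

check_pct <- function(x) {
  if (any(is.na(x) | x < 0 | x > 100)) {
    stop("stenosis_pct must lie in [0, 100]", call. = FALSE)
  }
  invisible(x)
}

#' Grade a lesion's stenosis on the 0-3 scale
#'
#' Grades recorded plaques: 1 (mild) below the obstructive cut, 2
#' (moderate/obstructive) from the obstructive cut up to and including
#' the severe cut, 3 (severe) strictly above it.  Grade 0 is reserved for
#' segments without plaque and is never returned for a recorded lesion,
#' so any plaque contributes at least 1 to the SSS.
#'
#' @param stenosis_pct numeric vector of luminal diameter reductions in
#'   percent, in \[0, 100\].
#' @param config a [ccta_config()] supplying the grade boundaries.
#' @return Integer vector of grades in `{1, 2, 3}`.
#' @examples
#' grade_lesion(c(30, 50, 70, 71))   # 1 2 2 3
#' @export
grade_lesion <- function(stenosis_pct, config = ccta_config()) {
  check_pct(stenosis_pct)
  g <- 1L + (stenosis_pct >= config$obstructive_cut) +
    (stenosis_pct > config$severe_cut)
  as.integer(g)
}

#' Is a stenosis obstructive?
#'
#' Obstructive stenosis (OS) is a luminal diameter reduction of at least
#' the obstructive cut (default 50%); equivalent to a stenosis grade of 2
#' or more.
#'
#' @inheritParams grade_lesion
#' @return Logical vector.
#' @examples
#' is_obstructive(c(49.9, 50, 100))  # FALSE TRUE TRUE
#' @export
is_obstructive <- function(stenosis_pct, config = ccta_config()) {
  check_pct(stenosis_pct)
  stenosis_pct >= config$obstructive_cut
}

#' Segment involvement score (SIS)
#'
#' The number of coronary segments exhibiting plaque, irrespective of
#' stenosis degree (0-18).
#'
#' @param p a valid [ccta_patient()].
#' @return Integer count.
#' @export
compute_sis <- function(p) {
  check_patient(p)
  length(unique(p$lesions$segment))
}

#' Segment stenosis score (SSS)
#'
#' The sum over diseased segments of the 0-3 stenosis grade; a measure of
#' overall plaque burden.
#'
#' @inheritParams compute_sis
#' @param config a [ccta_config()].
#' @return Integer score.
#' @export
compute_sss <- function(p, config = ccta_config()) {
  check_patient(p)
  sum(grade_lesion(p$lesions$stenosis_pct, config))
}

#' Stenosis coefficient (SC)
#'
#' The ratio SSS/SIS, reflecting the average per-segment stenosis degree;
#' defined as 0 when SIS is 0.
#'
#' @param sis,sss the segment involvement and stenosis scores.
#' @return Numeric; 0 when `sis` is 0, otherwise in \[1, 3\].
#' @examples
#' compute_sc(6, 6)   # 1
#' compute_sc(4, 10)  # 2.5
#' @export
compute_sc <- function(sis, sss) {
  stopifnot(length(sis) == 1L, length(sss) == 1L, sis >= 0, sss >= 0)
  if (sis == 0) {
    if (sss != 0) stop("SSS must be 0 when SIS is 0", call. = FALSE)
    return(0)
  }
  if (sss < sis || sss > 3 * sis) {
    stop("inconsistent scores: SIS <= SSS <= 3*SIS must hold",
         call. = FALSE)
  }
  sss / sis
}

#' Severe proximal plaque (SPP) flag
#'
#' TRUE when any lesion in the left main or the proximal LAD, LCx or RCA
#' segment is severe (stenosis strictly above the severe cut, default
#' 70%).
#'
#' @inheritParams compute_sss
#' @return Logical flag.
#' @export
compute_spp <- function(p, config = ccta_config()) {
  check_patient(p)
  les <- p$lesions
  any(les$segment %in% .spp_segments &
        les$stenosis_pct > config$severe_cut)
}

#' Partial CT-LeSc of one lesion
#'
#' The per-lesion contribution to the CCTA-adapted Leaman score:
#' localization weight (dominance-dependent) times a composition factor
#' (1 for calcified, 1.5 for non-calcified or mixed plaque) times a
#' stenosis factor (1 for obstructive, 0.615 for non-obstructive
#' lesions).
#'
#' @param segment segment name, canonical or printable.
#' @param composition `"calcified"`, `"non_calcified"` or `"mixed"`.
#' @param stenosis_pct luminal diameter reduction in percent.
#' @param dominance the patient's dominance.
#' @param config a [ccta_config()].
#' @return Numeric partial score (full precision).
#' @examples
#' lesion_ct_lesc("left_main", "mixed", 30, "right")       # 4.6125
#' lesion_ct_lesc("lcx_proximal", "calcified", 30, "right") # 0.9225
#' @export
lesion_ct_lesc <- function(segment, composition, stenosis_pct, dominance,
                           config = ccta_config()) {
  w <- segment_weight(segment, dominance)
  comp <- canonical_composition(composition)
  comp_factor <- ifelse(comp == "calcified", 1, 1.5)
  sten_factor <- ifelse(is_obstructive(stenosis_pct, config), 1, 0.615)
  w * comp_factor * sten_factor
}

#' Patient-level CT-LeSc
#'
#' The sum of the partial CT-LeSc of all diseased segments.  Under
#' `"paper_2dp"` rounding each partial is rounded half-up to two decimals
#' before summing, as on clinical worksheets; `"full_precision"` keeps
#' exact arithmetic throughout.
#'
#' @inheritParams compute_sss
#' @param rounding overrides `config$rounding` when given.
#' @return Numeric score; 0 when the patient has no lesions.
#' @export
patient_ct_lesc <- function(p, config = ccta_config(), rounding = NULL) {
  check_patient(p)
  rounding <- if (is.null(rounding)) config$rounding else
    match.arg(rounding, c("full_precision", "paper_2dp"))
  les <- p$lesions
  if (!nrow(les)) return(0)
  partial <- lesion_ct_lesc(les$segment, les$composition,
                            les$stenosis_pct, p$dominance, config)
  if (rounding == "paper_2dp") partial <- round_half_up(partial, 2)
  sum(partial)
}

#' Score one patient
#'
#' Computes the full score panel: SIS, SSS, SC, SPP flag, CT-LeSc (in the
#' configured rounding mode), the per-segment partial CT-LeSc values, and
#' whether any lesion is obstructive.
#'
#' @inheritParams compute_sss
#' @return An object of class `score_panel`: a list with elements
#'   `patient_id`, `sis`, `sss`, `sc`, `spp_positive`, `ct_lesc`,
#'   `has_obstructive` and `partial_lesc` (named numeric vector, in the
#'   configured rounding mode).
#' @examples
#' p <- example_patient()
#' score_patient(p, ccta_config(rounding = "paper_2dp"))
#' @export
score_patient <- function(p, config = ccta_config()) {
  check_patient(p)
  les <- p$lesions
  sis <- length(unique(les$segment))
  sss <- if (nrow(les)) sum(grade_lesion(les$stenosis_pct, config)) else 0L
  partial <- if (nrow(les)) {
    stats::setNames(
      lesion_ct_lesc(les$segment, les$composition, les$stenosis_pct,
                     p$dominance, config),
      les$segment)
  } else numeric()
  if (config$rounding == "paper_2dp") partial <- round_half_up(partial, 2)
  structure(
    list(patient_id = p$patient_id,
         sis = as.integer(sis),
         sss = as.integer(sss),
         sc = compute_sc(sis, sss),
         spp_positive = compute_spp(p, config),
         ct_lesc = sum(partial),
         has_obstructive = nrow(les) > 0 &&
           any(is_obstructive(les$stenosis_pct, config)),
         partial_lesc = partial),
    class = "score_panel"
  )
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("Score panel for patient '%s'\n", x$patient_id))
  cat(sprintf("  SIS %d | SSS %d | SC %.2f | SPP %s | CT-LeSc %.2f | OS %s\n",
              x$sis, x$sss, x$sc,
              if (x$spp_positive) "positive" else "negative",
              x$ct_lesc, if (x$has_obstructive) "yes" else "no"))
  invisible(x)
}

#' Score a whole cohort
#'
#' Applies [score_patient()] to a list of patients (or a lesion table in
#' the reader's canonical form, see [as_patients()]) and stacks the
#' panels into one data frame.
#'
#' @param patients a list of [ccta_patient()] objects, or a lesion data
#'   frame with columns `patient_id`, `dominance`, `segment`,
#'   `stenosis_pct`, `composition`.
#' @param config a [ccta_config()].
#' @return A data frame of class `ccta_scores` with one row per patient
#'   and columns `patient_id`, `sis`, `sss`, `sc`, `spp_positive`,
#'   `ct_lesc`, `has_obstructive`.
#' @export
score_cohort <- function(patients, config = ccta_config()) {
  if (is.data.frame(patients)) patients <- as_patients(patients)
  stopifnot(is.list(patients),
            all(vapply(patients, inherits, logical(1), "ccta_patient")))
  panels <- lapply(patients, score_patient, config = config)
  out <- data.frame(
    patient_id = vapply(panels, `[[`, character(1), "patient_id"),
    sis = vapply(panels, `[[`, integer(1), "sis"),
    sss = vapply(panels, `[[`, integer(1), "sss"),
    sc = vapply(panels, `[[`, numeric(1), "sc"),
    spp_positive = vapply(panels, `[[`, logical(1), "spp_positive"),
    ct_lesc = vapply(panels, `[[`, numeric(1), "ct_lesc"),
    has_obstructive = vapply(panels, `[[`, logical(1), "has_obstructive"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ccta_scores", "data.frame")
  out
}

#' @export
print.ccta_scores <- function(x, ...) {
  cat(sprintf("CCTA score panel for %d patient(s)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.ccta_scores <- function(object, ...) {
  num <- c("sis", "sss", "sc", "ct_lesc")
  cat(sprintf("Cohort of %d patient(s)\n", nrow(object)))
  for (v in num) {
    s <- summarize_variable(object[[v]], kind = "nonnormal")
    cat(sprintf("  %-8s median %.2f (IQR %.2f, %.2f)\n",
                toupper(v), s$median, s$q1, s$q3))
  }
  cat(sprintf("  SPP positive    %d (%.1f%%)\n", sum(object$spp_positive),
              100 * mean(object$spp_positive)))
  cat(sprintf("  any obstructive %d (%.1f%%)\n", sum(object$has_obstructive),
              100 * mean(object$has_obstructive)))
  invisible(object)
}

#' The packaged worked-example patient
#'
#' A right-dominant patient with six mild (non-obstructive) lesions:
#' mixed plaques in the left main and the proximal and mid LAD, and
#' calcified plaques in the 1st diagonal, proximal LCx and proximal RCA.
#' With two-decimal worksheet rounding the partial CT-LeSc values are
#' 4.61, 3.23, 2.31, 0.62, 0.92 and 0.62, total 12.31; SIS = SSS = 6,
#' SC = 1, SPP negative.
#'
#' @return A [ccta_patient()] built from the packaged lesion fixture.
#' @examples
#' score_patient(example_patient(), ccta_config(rounding = "paper_2dp"))
#' @export
example_patient <- function() {
  path <- system.file("extdata", "worked_example_lesions.csv",
                      package = "cctascore", mustWork = TRUE)
  read_lesion_table(path)[[1L]]
}
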