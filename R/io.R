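# Delimited-text interchange: lesion tables, clinical tables, score
# tables, comparison reports.  Comma-separated, UTF-8, header row
# mandatory, decimal point.  Stenosis must be on the percent scale;
# values that look like fractions (in (0, 1]) are rejected, never
# rescaled.

#' Group a lesion table into patients
#'
#' Splits a canonical lesion data frame (`patient_id`, `dominance`,
#' `segment`, `stenosis_pct`, `composition`) into one [ccta_patient()]
#' per patient.  Duplicate segment rows for a patient are collapsed to
#' the maximal stenosis and the worst composition (mixed >
#' non-calcified > calcified) with a warning; conflicting dominance
#' values for a patient are an error.
#'
#' @param lesions lesion data frame.
#' @return Named list of [ccta_patient()] objects, in order of first
#'   appearance.
#' @export
as_patients <- function(lesions) {
  stopifnot(is.data.frame(lesions),
            all(c("patient_id", "dominance", "segment", "stenosis_pct",
                  "composition") %in% names(lesions)))
  lesions$patient_id <- as.character(lesions$patient_id)
  ids <- unique(lesions$patient_id)
  comp_rank <- c(calcified = 1, non_calcified = 2, mixed = 3)
  out <- list()
  for (id in ids) {
    rows <- lesions[lesions$patient_id == id, , drop = FALSE]
    dom <- unique(canonical_dominance(rows$dominance))
    if (length(dom) != 1L) {
      stop(sprintf("patient '%s' has conflicting dominance values: %s",
                   id, paste(dom, collapse = ", ")), call. = FALSE)
    }
    rows$segment <- canonical_segment(rows$segment)
    rows$composition <- canonical_composition(rows$composition)
    if (anyDuplicated(rows$segment)) {
      dup <- unique(rows$segment[duplicated(rows$segment)])
      warning(sprintf(
        "patient '%s': multiple rows for segment(s) %s collapsed to %s",
        id, paste(dup, collapse = ", "),
        "maximal stenosis / worst composition"), call. = FALSE)
      rows <- do.call(rbind, lapply(split(rows, rows$segment), function(d) {
        data.frame(patient_id = d$patient_id[1], dominance = d$dominance[1],
                   segment = d$segment[1],
                   stenosis_pct = max(d$stenosis_pct),
                   composition = d$composition[which.max(
                     comp_rank[d$composition])],
                   stringsAsFactors = FALSE)
      }))
    }
    out[[id]] <- ccta_patient(id, dom,
                              rows[, c("segment", "stenosis_pct",
                                       "composition")])
  }
  out
}

#' Read a lesion table
#'
#' Reads a CSV with header `patient_id, dominance, segment,
#' stenosis_pct, composition` (segments in canonical or printable form)
#' and returns one validated patient per id.  Malformed rows are
#' reported with their line numbers; stenosis values in (0, 1] are
#' rejected as probable fraction/percent unit errors.
#'
#' @param path file path.
#' @return Named list of [ccta_patient()] objects.
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "dominance", "segment", "stenosis_pct",
                "composition")
  if (!all(required %in% names(df))) {
    stop("lesion table must have header columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) return(list())
  df$stenosis_pct <- suppressWarnings(as.numeric(df$stenosis_pct))
  bad <- which(is.na(df$stenosis_pct) | df$stenosis_pct < 0 |
                 df$stenosis_pct > 100)
  if (length(bad)) {
    stop("non-numeric or out-of-range stenosis_pct at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  frac <- which(df$stenosis_pct > 0 & df$stenosis_pct <= 1)
  if (length(frac)) {
    stop("stenosis_pct looks like a fraction (values in (0, 1]) at data ",
         "row(s): ", paste(frac, collapse = ", "),
         "; supply percentages on the 0-100 scale", call. = FALSE)
  }
  # canonicalize row by row so errors carry line numbers
  for (i in seq_len(nrow(df))) {
    seg <- try(canonical_segment(df$segment[i]), silent = TRUE)
    if (inherits(seg, "try-error")) {
      stop(sprintf("data row %d: %s", i,
                   conditionMessage(attr(seg, "condition"))),
           call. = FALSE)
    }
    df$segment[i] <- seg
  }
  patients <- as_patients(df)
  for (p in patients) {
    v <- validate_patient(p)
    if (length(v)) {
      stop(sprintf("patient '%s' fails validation:\n  %s", p$patient_id,
                   paste(v, collapse = "\n  ")), call. = FALSE)
    }
  }
  patients
}

#' Write a lesion table
#'
#' Inverse of [read_lesion_table()]: one CSV row per lesion in the
#' canonical column order.
#'
#' @param patients list of [ccta_patient()] objects or a `ccta_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(patients, path) {
  if (inherits(patients, "ccta_cohort")) {
    utils::write.csv(patients$lesions, path, row.names = FALSE,
                     quote = FALSE)
    return(invisible(path))
  }
  rows <- lapply(patients, function(p) {
    if (!nrow(p$lesions)) return(NULL)
    data.frame(patient_id = p$patient_id, dominance = p$dominance,
               p$lesions, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(Filter(Negate(is.null), rows),
                         make.row.names = FALSE))
  if (is.null(df)) {
    df <- data.frame(patient_id = character(), dominance = character(),
                     segment = character(), stenosis_pct = numeric(),
                     composition = character())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' Plain CSV with the columns of [clinical_columns()] (extra columns,
#' e.g. `group`, are preserved).
#'
#' @param path file path.
#' @return `read_clinical_table()`: a data frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) {
    stop("clinical table must contain a patient_id column", call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' @rdname read_clinical_table
#' @param records clinical data frame.
#' @export
write_clinical_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a score table
#'
#' @param scores a `ccta_scores` data frame from [score_cohort()].
#' @param path output file path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Reference stenotic-segment counts
#'
#' The packaged group-level tabulation of stenotic segments (per
#' coronary segment, by obstructive severity, and by plaque
#' composition) from the 215-patient diabetes screening cohort this
#' scoring system targets: a control group and three UKPDS risk tiers.
#' Shipped as plain text so the arithmetic behind the headline
#' percentages can be audited.
#'
#' @return A list of data frames `segments`, `severity`, `composition`,
#'   each with count columns `control`, `low`, `moderate`, `high`.
#' @export
reference_segment_counts <- function() {
  path <- system.file("extdata", "segment_counts_reference.csv",
                      package = "cctascore", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_block <- function(b) {
    d <- df[df$block == b, c("category", "control", "low", "moderate",
                             "high")]
    rownames(d) <- NULL
    d
  }
  list(segments = split_block("segment"),
       severity = split_block("severity"),
       composition = split_block("composition"))
}

#' Headline arithmetic on a segment-count tabulation
#'
#' From per-group counts, derives the totals and percentages used as
#' headline findings: the overall number of stenotic segments, the
#' percentage of obstructive segments among the diabetes groups and
#' among controls, and the share of all stenotic segments that sit in
#' the proximal LAD.
#'
#' @param counts a list as returned by [reference_segment_counts()].
#' @return A list with `total_segments`, `dm_segments`,
#'   `control_segments`, `pct_obstructive_dm`, `pct_obstructive_control`
#'   and `pct_lad_proximal` (percentages rounded to the nearest whole
#'   percent, as conventionally reported).
#' @examples
#' summarize_segment_counts(reference_segment_counts())
#' @export
summarize_segment_counts <- function(counts = reference_segment_counts()) {
  seg <- counts$segments
  sev <- counts$severity
  group_cols <- c("control", "low", "moderate", "high")
  dm_cols <- c("low", "moderate", "high")
  totals <- colSums(seg[, group_cols])
  obstructive <- unlist(sev[sev$category == "Obstructive stenosis",
                            group_cols])
  lad_prox <- unlist(seg[seg$category == "LAD proximal", group_cols])
  list(
    total_segments = sum(totals),
    dm_segments = sum(totals[dm_cols]),
    control_segments = unname(totals["control"]),
    pct_obstructive_dm = unname(round(
      100 * sum(obstructive[dm_cols]) / sum(totals[dm_cols]))),
    pct_obstructive_control = unname(round(
      100 * obstructive[["control"]] / totals[["control"]])),
    pct_lad_proximal = unname(round(100 * sum(lad_prox) / sum(totals)))
  )
}
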