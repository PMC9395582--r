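# 18-segment SCCT coronary model: segment identifiers, dominance patterns,
# and the dominance-dependent CT-LeSc localization weight table shipped as
# a plain-text file under inst/extdata so it can be audited line by line.

.segment_map <- data.frame(
  token = c(
    "rca_proximal", "rca_mid", "rca_distal", "pda",
    "left_main", "lad_proximal", "lad_mid", "lad_distal",
    "diagonal_1", "diagonal_2",
    "lcx_proximal", "obtuse_marginal_1", "lcx_distal", "obtuse_marginal_2",
    "pda_from_lca", "pl_branch_from_lca", "pl_branch_from_rca",
    "intermediate_branch"
  ),
  printable = c(
    "RCA proximal", "RCA mid", "RCA distal", "PDA",
    "Left main", "LAD proximal", "LAD mid", "LAD distal",
    "1st diagonal", "2nd diagonal",
    "LCx proximal", "1st obtuse marginal", "LCx distal",
    "2nd obtuse marginal",
    "PDA from LCA", "PL branch from LCA", "PL branch from RCA",
    "Intermediate branch"
  ),
  stringsAsFactors = FALSE
)

.dominance_levels <- c("right", "left", "balanced")
.composition_levels <- c("calcified", "non_calcified", "mixed")

#' The 18 SCCT coronary segments
#'
#' @param printable if `TRUE`, return the human-readable segment names;
#'   otherwise the canonical snake-case tokens used throughout the package.
#' @return Character vector of length 18.
#' @examples
#' coronary_segments()
#' coronary_segments(printable = TRUE)
#' @export
coronary_segments <- function(printable = FALSE) {
  if (printable) .segment_map$printable else .segment_map$token
}

#' Coronary dominance patterns
#'
#' Dominance records which artery supplies the posterior descending
#' territory; it reweights the posterior segments in the CT-LeSc.
#'
#' @return `c("right", "left", "balanced")`.
#' @export
dominance_levels <- function() .dominance_levels

#' Plaque composition categories
#'
#' @return `c("calcified", "non_calcified", "mixed")`.
#' @export
composition_levels <- function() .composition_levels

#' Canonicalize segment names
#'
#' Maps either the canonical tokens (e.g. `"lad_proximal"`) or the
#' printable names (e.g. `"LAD proximal"`) to canonical tokens.  Matching
#' of printable names is case-insensitive.
#'
#' @param x character vector of segment names in either form.
#' @return Character vector of canonical tokens.
#' @examples
#' canonical_segment(c("LAD proximal", "left_main"))
#' @export
canonical_segment <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  hit_tok <- match(x, .segment_map$token)
  hit_pr <- match(tolower(x), tolower(.segment_map$printable))
  out[!is.na(hit_tok)] <- .segment_map$token[hit_tok[!is.na(hit_tok)]]
  fill <- is.na(out) & !is.na(hit_pr)
  out[fill] <- .segment_map$token[hit_pr[fill]]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf(
      "unknown coronary segment(s): %s\naccepted names: %s",
      paste(shQuote(bad), collapse = ", "),
      paste(.segment_map$token, collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Printable name of a canonical segment token
#'
#' @param token character vector of canonical tokens.
#' @return Character vector of printable segment names.
#' @export
segment_printable <- function(token) {
  i <- match(token, .segment_map$token)
  if (anyNA(i)) stop("unknown segment token(s): ",
                     paste(shQuote(token[is.na(i)]), collapse = ", "),
                     call. = FALSE)
  .segment_map$printable[i]
}

canonical_dominance <- function(x) {
  x <- tolower(as.character(x))
  if (!all(x %in% .dominance_levels)) {
    stop("dominance must be one of: ",
         paste(.dominance_levels, collapse = ", "), call. = FALSE)
  }
  x
}

canonical_composition <- function(x) {
  x <- tolower(gsub("[- ]", "_", as.character(x)))
  if (!all(x %in% .composition_levels)) {
    stop("composition must be one of: ",
         paste(.composition_levels, collapse = ", "),
         " (hyphenated forms accepted)", call. = FALSE)
  }
  x
}

#' The CT-LeSc localization weight table
#'
#' Reads (once per session) the packaged segment-by-dominance weight
#' table.  Cells that are anatomically absent for a dominance pattern
#' (e.g. the posterior descending artery from the left coronary under
#' right dominance) carry `NA` and are treated as hard errors by
#' [segment_weight()], never as weight zero.
#'
#' @return A data frame with columns `segment` (canonical token),
#'   `dominance` and `weight` (`NA` for not-applicable cells); 54 rows.
#' @examples
#' head(lesc_weight_table())
#' @export
lesc_weight_table <- function() {
  if (is.null(.cctascore_env$weights)) {
    path <- system.file("extdata", "ct_lesc_weights.csv",
                        package = "cctascore", mustWork = TRUE)
    w <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
    w$weight <- suppressWarnings(as.numeric(ifelse(w$weight == "na",
                                                   NA, w$weight)))
    stopifnot(nrow(w) == 54L,
              !anyDuplicated(paste(w$segment, w$dominance)))
    .cctascore_env$weights <- w
  }
  .cctascore_env$weights
}

#' Localization weight of a segment under a dominance pattern
#'
#' @param segment segment name(s), canonical or printable.
#' @param dominance dominance value(s) (`"right"`, `"left"`,
#'   `"balanced"`); recycled against `segment`.
#' @return Numeric vector of weights.
#' @section Errors:
#' Requesting a weight for an anatomically absent (not-applicable) cell
#' raises an error of class `notApplicableSegment`: a lesion annotated on
#' such a segment indicates corrupt input, and silently scoring it with
#' weight zero would drop plaque burden.
#' @examples
#' segment_weight("lad_proximal", "right")   # 3.5
#' segment_weight("Left main", "left")       # 6
#' @export
segment_weight <- function(segment, dominance) {
  seg <- canonical_segment(segment)
  dom <- canonical_dominance(dominance)
  n <- max(length(seg), length(dom))
  seg <- rep_len(seg, n)
  dom <- rep_len(dom, n)
  w <- lesc_weight_table()
  i <- match(paste(seg, dom), paste(w$segment, w$dominance))
  out <- w$weight[i]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(structure(
      class = c("notApplicableSegment", "error", "condition"),
      list(message = sprintf(
             "segment '%s' is not applicable under %s dominance",
             seg[bad], dom[bad]),
           call = sys.call(-1))
    ))
  }
  out
}

#' Segments applicable under a dominance pattern
#'
#' @param dominance a single dominance value.
#' @return Character vector of canonical tokens for which a weight exists.
#' @export
applicable_segments <- function(dominance) {
  dom <- canonical_dominance(dominance)
  stopifnot(length(dom) == 1L)
  w <- lesc_weight_table()
  w$segment[w$dominance == dom & !is.na(w$weight)]
}

#' Build a per-patient CCTA lesion record
#'
#' A `ccta_patient` holds the patient's coronary dominance and one lesion
#' row per diseased segment (per-segment maximal stenosis and the plaque
#' composition).  Construction canonicalizes names but does not enforce
#' the anatomical invariants; use [validate_patient()] for that.
#'
#' @param patient_id scalar identifier.
#' @param dominance `"right"`, `"left"` or `"balanced"`.
#' @param lesions a data frame with columns `segment`, `stenosis_pct` and
#'   `composition`, one row per lesion; may have zero rows.
#' @return An object of class `ccta_patient`.
#' @examples
#' p <- ccta_patient("p1", "right",
#'                   data.frame(segment = "lad_proximal",
#'                              stenosis_pct = 60,
#'                              composition = "calcified"))
#' validate_patient(p)
#' @export
ccta_patient <- function(patient_id, dominance,
                         lesions = data.frame(segment = character(),
                                              stenosis_pct = numeric(),
                                              composition = character())) {
  stopifnot(length(patient_id) == 1L)
  dominance <- canonical_dominance(dominance)
  stopifnot(length(dominance) == 1L)
  stopifnot(is.data.frame(lesions),
            all(c("segment", "stenosis_pct", "composition") %in%
                  names(lesions)))
  lesions <- data.frame(
    segment = if (nrow(lesions)) canonical_segment(lesions$segment)
              else character(),
    stenosis_pct = as.numeric(lesions$stenosis_pct),
    composition = if (nrow(lesions)) canonical_composition(lesions$composition)
                  else character(),
    stringsAsFactors = FALSE
  )
  structure(
    list(patient_id = as.character(patient_id),
         dominance = dominance,
         lesions = lesions),
    class = "ccta_patient"
  )
}

#' @export
print.ccta_patient <- function(x, ...) {
  cat(sprintf("CCTA patient '%s' (%s dominance), %d lesion(s)\n",
              x$patient_id, x$dominance, nrow(x$lesions)))
  if (nrow(x$lesions)) {
    df <- x$lesions
    df$segment <- segment_printable(df$segment)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Validate a patient's lesion set against the coronary model
#'
#' Checks the anatomical invariants: at most one lesion per segment, no
#' lesion on a segment that is not applicable under the patient's
#' dominance, and stenosis percentages within \[0, 100\].  Validation
#' always returns (it never raises), so readers can collect and report
#' every problem at once.
#'
#' @param p a [ccta_patient()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_patient <- function(p) {
  stopifnot(inherits(p, "ccta_patient"))
  out <- character()
  les <- p$lesions
  if (!nrow(les)) return(out)
  dup <- unique(les$segment[duplicated(les$segment)])
  for (s in dup) {
    out <- c(out, sprintf("segment '%s': duplicate lesion rows", s))
  }
  ok <- applicable_segments(p$dominance)
  for (s in unique(les$segment[!les$segment %in% ok])) {
    out <- c(out, sprintf(
      "segment '%s': not applicable under %s dominance", s, p$dominance))
  }
  bad <- les$segment[is.na(les$stenosis_pct) | les$stenosis_pct < 0 |
                       les$stenosis_pct > 100]
  for (s in unique(bad)) {
    out <- c(out, sprintf(
      "segment '%s': stenosis_pct outside [0, 100]", s))
  }
  out
}
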