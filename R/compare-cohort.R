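# One-call comparison battery over a scored, grouped cohort, shaped like
# the report tables of a screening study: per-group score summaries,
# omnibus + post-hoc rank tests, chi-squared on the SPP ratio, group
# odds ratios for the dichotomized scores, and the stenotic-segment
# tabulation.

#' Compare scores across cohort groups
#'
#' Runs the full battery against a reference group: median (IQR)
#' summaries and Kruskal-Wallis omnibus + Bonferroni post-hoc tests for
#' SIS, SSS, SC and CT-LeSc; a Pearson chi-squared test on the SPP
#' positive ratio; and binary logistic odds ratios (vs the reference
#' group) for the dichotomized panel (SIS > 3, SSS > 5, CT-LeSc > 8.7,
#' obstructive stenosis).
#'
#' @param scores a `ccta_scores` data frame from [score_cohort()].
#' @param group group label per patient: a vector aligned with `scores`
#'   rows or a named vector indexed by `patient_id`.
#' @param reference label of the reference group (default the first
#'   level).
#' @param lesions optional lesion data frame; when supplied the
#'   stenotic-segment tabulation is included.
#' @param config a [ccta_config()].
#' @return An object of class `ccta_comparison`: a list with elements
#'   `summaries`, `score_tests`, `posthoc`, `spp_test`, `odds`,
#'   `tabulation` (or `NULL`), `reference`, `alpha`.
#' @export
compare_cohort <- function(scores, group, reference = NULL,
                           lesions = NULL, config = ccta_config()) {
  stopifnot(inherits(scores, "ccta_scores") || is.data.frame(scores))
  if (!is.null(names(group))) group <- group[scores$patient_id]
  group <- as.factor(group)
  stopifnot(length(group) == nrow(scores))
  if (nlevels(group) < 2) {
    stop("at least 2 groups are required for a comparison",
         call. = FALSE)
  }
  if (is.null(reference)) reference <- levels(group)[1]
  stopifnot(reference %in% levels(group))

  vars <- c("sis", "sss", "sc", "ct_lesc")
  summaries <- lapply(stats::setNames(vars, vars), function(v) {
    lapply(split(scores[[v]], group), summarize_variable,
           kind = "nonnormal", config = config)
  })
  summaries$spp_positive <- lapply(split(scores$spp_positive, group),
                                   summarize_variable,
                                   kind = "categorical", config = config)

  score_tests <- list(); posthoc <- list()
  for (v in vars) {
    res <- compare_multi(split(scores[[v]], group), posthoc = TRUE,
                         config = config)
    score_tests[[v]] <- res[[1]]
    posthoc[[v]] <- res[-1]
  }
  spp_tab <- table(group, factor(scores$spp_positive,
                                 levels = c(FALSE, TRUE)))
  spp_test <- suppressWarnings(compare_categorical(spp_tab))

  flags <- dichotomize_panel(scores, config)
  odds <- lapply(
    stats::setNames(c("sis_high", "sss_high", "lesc_high", "os"),
                    c("sis_high", "sss_high", "lesc_high", "os")),
    function(f) {
      if (length(unique(flags[[f]])) < 2) return(NULL)
      logistic_or(flags[[f]], group, reference)
    })

  tabulation <- if (!is.null(lesions)) {
    tabulate_lesions(lesions,
                     stats::setNames(as.character(group),
                                     scores$patient_id),
                     config)
  }
  structure(
    list(summaries = summaries, score_tests = score_tests,
         posthoc = posthoc, spp_test = spp_test, odds = odds,
         tabulation = tabulation, reference = reference,
         alpha = config$alpha, groups = levels(group)),
    class = "ccta_comparison"
  )
}

#' @export
print.ccta_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison across groups: %s (reference: %s)\n",
              paste(x$groups, collapse = ", "), x$reference))
  for (v in names(x$score_tests)) {
    t <- x$score_tests[[v]]
    lab <- vapply(x$summaries[[v]], `[[`, character(1), "label")
    cat(sprintf("  %-8s %s | H = %.3f, p = %.4g%s\n", toupper(v),
                paste(lab, collapse = " | "), t$statistic, t$p_value,
                if (t$p_value < x$alpha) " *" else ""))
  }
  lab <- vapply(x$summaries$spp_positive, `[[`, character(1), "label")
  cat(sprintf("  SPP+     %s | chi2 = %.3f, p = %.4g%s\n",
              paste(lab, collapse = " | "), x$spp_test$statistic,
              x$spp_test$p_value,
              if (x$spp_test$p_value < x$alpha) " *" else ""))
  cat("Odds ratios vs reference:\n")
  for (f in names(x$odds)) {
    if (is.null(x$odds[[f]])) next
    o <- x$odds[[f]]
    cat(sprintf("  %-9s %s\n", f, paste(
      sprintf("%s %.3f (%.3f-%.3f)", o$group, o$or, o$ci_lower,
              o$ci_upper), collapse = " | ")))
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits delimited-text tables (score summaries with omnibus tests,
#' post-hoc pairs, odds ratios, and the segment tabulation when
#' present) plus one machine-readable JSON report.
#'
#' @param x a `ccta_comparison`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_comparison_report <- function(x, dir) {
  stopifnot(inherits(x, "ccta_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sum_rows <- do.call(rbind, lapply(names(x$summaries), function(v) {
    lab <- vapply(x$summaries[[v]], `[[`, character(1), "label")
    stat <- if (v == "spp_positive") x$spp_test else x$score_tests[[v]]
    data.frame(variable = v, t(lab), statistic = stat$statistic,
               p_value = stat$p_value, test = stat$test,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.csv(sum_rows, file.path(dir, "score_comparison.csv"),
                   row.names = FALSE)

  ph_rows <- do.call(rbind, lapply(names(x$posthoc), function(v) {
    do.call(rbind, lapply(x$posthoc[[v]], function(r) {
      data.frame(variable = v, group_a = r$pair[1], group_b = r$pair[2],
                 z = r$statistic, p_raw = r$p_raw,
                 p_adjusted = r$p_value, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(ph_rows, file.path(dir, "posthoc_pairs.csv"),
                   row.names = FALSE)

  or_rows <- do.call(rbind, lapply(names(x$odds), function(f) {
    if (is.null(x$odds[[f]])) return(NULL)
    data.frame(finding = f, as.data.frame(x$odds[[f]]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(or_rows)) {
    utils::write.csv(or_rows, file.path(dir, "odds_ratios.csv"),
                     row.names = FALSE)
  }
  if (!is.null(x$tabulation)) {
    tab <- x$tabulation
    seg <- data.frame(segment = segment_printable(rownames(tab$segments)),
                      tab$segments, check.names = FALSE)
    utils::write.csv(seg, file.path(dir, "segment_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(severity = rownames(tab$severity),
                                tab$severity, check.names = FALSE),
                     file.path(dir, "severity_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(composition = rownames(tab$composition),
                                tab$composition, check.names = FALSE),
                     file.path(dir, "composition_counts.csv"),
                     row.names = FALSE)
  }

  report <- list(
    groups = x$groups, reference = x$reference, alpha = x$alpha,
    score_tests = lapply(x$score_tests, function(t) {
      list(statistic = t$statistic, p_value = t$p_value, test = t$test)
    }),
    spp_test = list(statistic = x$spp_test$statistic,
                    p_value = x$spp_test$p_value),
    posthoc = ph_rows,
    odds = lapply(Filter(Negate(is.null), x$odds), as.data.frame)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
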