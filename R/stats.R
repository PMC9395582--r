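# Group-comparison battery for scored cohorts: descriptive summaries,
# two-group Mann-Whitney (exact by enumeration at small n, tie-corrected
# normal approximation otherwise), Kruskal-Wallis with Bonferroni-adjusted
# rank post-hoc tests, Pearson chi-squared, score dichotomization, and
# binary logistic odds ratios with Wald intervals.

comparison_result <- function(statistic, p_value, test, adjusted = FALSE,
                              ...) {
  structure(
    c(list(statistic = unname(statistic), p_value = unname(p_value),
           test = test, adjusted = adjusted), list(...)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, %sp = %.4g\n", x$test, x$statistic,
              if (isTRUE(x$adjusted)) "adjusted " else "", x$p_value))
  invisible(x)
}

#' Descriptive summary of one variable
#'
#' Normally distributed variables are summarized as mean +/- SD,
#' non-normal ones as median (Q1, Q3) with quartiles at the 25th/75th
#' percentiles under the configured percentile rule, and categorical
#' (logical) ones as n (%).
#'
#' @param values numeric or logical vector; must be non-empty.
#' @param kind `"normal"`, `"nonnormal"` or `"categorical"`.
#' @param config a [ccta_config()] (percentile rule).
#' @return A list with the summary fields and a preformatted `label`.
#' @examples
#' summarize_variable(c(1, 2, 3, 4, 5), "nonnormal")$label
#' @export
summarize_variable <- function(values,
                               kind = c("normal", "nonnormal",
                                        "categorical"),
                               config = ccta_config()) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to summarize",
                            call. = FALSE)
  switch(kind,
    normal = {
      m <- mean(values); s <- stats::sd(values)
      if (is.na(s)) s <- 0
      list(kind = kind, n = length(values), mean = m, sd = s,
           label = sprintf("%.1f ± %.1f", m, s))
    },
    nonnormal = {
      q <- stats::quantile(values, c(0.25, 0.5, 0.75),
                           type = config$quantile_type, names = FALSE)
      list(kind = kind, n = length(values), median = q[2],
           q1 = q[1], q3 = q[3],
           label = sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3]))
    },
    categorical = {
      k <- sum(as.logical(values))
      n <- length(values)
      list(kind = kind, n = n, count = k, pct = 100 * k / n,
           label = sprintf("%d (%.1f%%)", k, 100 * k / n))
    }
  )
}

# Mann-Whitney U of group x against group y, using mid-ranks.
mwu_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided p by full enumeration of the C(n1+n2, n1) group
# assignments of the pooled mid-ranks; two-sided extremity is measured
# as distance of U from its permutation mean n1*n2/2.
mwu_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  mu <- n1 * n2 / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Compare two groups (Mann-Whitney U test)
#'
#' Two-sided rank-sum comparison.  When the combined sample size is at
#' most `config$exact_max_n` the p-value is exact, computed by full
#' enumeration of group assignments over the pooled mid-ranks (so ties
#' are handled exactly); otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param config a [ccta_config()].
#' @return A `comparison_result` with the U statistic of the first group
#'   and fields `exact` and group sizes.
#' @examples
#' compare_two(c(1, 2, 3), c(4, 5, 6))$p_value   # exact 0.1
#' @export
compare_two <- function(x, y, config = ccta_config()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  u <- mwu_statistic(x, y)
  if (length(x) + length(y) <= config$exact_max_n) {
    p <- mwu_exact_p(x, y)
    comparison_result(u, p, "Mann-Whitney U (exact)", exact = TRUE,
                      n = c(length(x), length(y)))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    comparison_result(u, wt$p.value,
                      "Mann-Whitney U (normal approximation)",
                      exact = FALSE, n = c(length(x), length(y)))
  }
}

# SPSS-style post-hoc for Kruskal-Wallis: Dunn z-tests on the pooled
# mid-ranks with tie correction, Bonferroni-multiplied by the number of
# pairs.
dunn_pairwise <- function(groups) {
  k <- length(groups)
  labels <- names(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(pooled)
  n <- length(pooled)
  tie <- table(pooled)
  tie_term <- sum(tie^3 - tie) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  m <- k * (k - 1) / 2
  out <- vector("list", m)
  idx <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt((n * (n + 1) / 12 - tie_term) *
                   (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
      z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      p_raw <- 2 * stats::pnorm(-abs(z))
      idx <- idx + 1L
      out[[idx]] <- comparison_result(
        z, min(1, m * p_raw), "Dunn rank post-hoc (Bonferroni)",
        adjusted = TRUE, p_raw = p_raw,
        pair = c(labels[i], labels[j]), m = m)
    }
  }
  out
}

#' Compare several groups (Kruskal-Wallis, optional post-hoc)
#'
#' Omnibus tie-corrected Kruskal-Wallis test across k groups; with
#' `posthoc = TRUE` all k(k-1)/2 pairwise Dunn rank tests on the pooled
#' ranks are appended, Bonferroni-adjusted (multiplier k(k-1)/2, capped
#' at 1).
#'
#' @param groups a named list of non-empty numeric vectors (k >= 2).
#' @param posthoc append pairwise comparisons?
#' @param config a [ccta_config()].
#' @return A list of `comparison_result` objects; the first element is
#'   the omnibus test, the rest (if requested) the pairs in label order.
#' @export
compare_multi <- function(groups, posthoc = FALSE,
                          config = ccta_config()) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)),
              levels = names(groups))
  kw <- stats::kruskal.test(pooled, g)
  omnibus <- comparison_result(kw$statistic, kw$p.value,
                               "Kruskal-Wallis",
                               df = unname(kw$parameter))
  if (!posthoc) return(list(omnibus))
  c(list(omnibus), dunn_pairwise(groups))
}

#' Compare a contingency table (Pearson chi-squared)
#'
#' Pearson chi-squared without continuity correction, df = (r-1)(c-1).
#' A warning is attached (not an automatic switch to an exact test) when
#' any expected count falls below 5.
#'
#' @param table an r x c matrix of non-negative counts with a positive
#'   total.
#' @return A `comparison_result` with fields `df` and
#'   `low_expected_counts`.
#' @examples
#' compare_categorical(matrix(c(10, 10, 10, 10), 2))$statistic   # 0
#' @export
compare_categorical <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) <= 0) {
    stop("counts must be non-negative with a positive total",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  low <- any(ct$expected < 5)
  if (low) {
    warning("some expected counts are below 5; the chi-squared ",
            "approximation may be poor", call. = FALSE)
  }
  comparison_result(ct$statistic, ct$p.value,
                    "Pearson chi-squared", df = unname(ct$parameter),
                    low_expected_counts = low)
}

#' Dichotomize a score panel
#'
#' Applies the strict screening cut points: SIS > 3, SSS > 5, CT-LeSc >
#' 8.7, plus the obstructive-stenosis flag.  Thresholds come from the
#' configuration.
#'
#' @param panel a `score_panel` (from [score_patient()]) or a
#'   `ccta_scores` data frame.
#' @param config a [ccta_config()].
#' @return A data frame with logical columns `sis_high`, `sss_high`,
#'   `lesc_high`, `os` (one row per patient).
#' @export
dichotomize_panel <- function(panel, config = ccta_config()) {
  if (inherits(panel, "score_panel")) {
    panel <- data.frame(patient_id = panel$patient_id, sis = panel$sis,
                        sss = panel$sss, ct_lesc = panel$ct_lesc,
                        has_obstructive = panel$has_obstructive)
  }
  stopifnot(is.data.frame(panel),
            all(c("sis", "sss", "ct_lesc", "has_obstructive") %in%
                  names(panel)))
  data.frame(
    patient_id = panel$patient_id,
    sis_high = panel$sis > config$sis_threshold,
    sss_high = panel$sss > config$sss_threshold,
    lesc_high = panel$ct_lesc > config$lesc_threshold,
    os = as.logical(panel$has_obstructive),
    stringsAsFactors = FALSE
  )
}

#' Group odds ratios from binary logistic regression
#'
#' Fits `outcome ~ group` by maximum likelihood with indicator coding
#' against a reference group and returns, per non-reference group, the
#' odds ratio, Wald 95% confidence interval and Wald p-value.  Complete
#' or quasi-complete separation is detected (degenerate fitted
#' probabilities or exploding standard errors) and flagged rather than
#' silently reported as a finite interval.
#'
#' @param outcome logical (or 0/1) vector, one element per patient.
#' @param group factor or character vector of group labels.
#' @param reference label of the reference group.
#' @return A data frame of class `odds_result` with columns `group`,
#'   `or`, `ci_lower`, `ci_upper`, `p_value`, `separation`.
#' @examples
#' out <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 20))
#' grp <- rep(c("control", "dm"), each = 40)
#' logistic_or(out, grp, reference = "control")
#' @export
logistic_or <- function(outcome, group, reference) {
  outcome <- as.logical(outcome)
  group <- as.factor(group)
  stopifnot(reference %in% levels(group), nlevels(group) >= 2)
  if (length(unique(outcome)) < 2) {
    stop("outcome does not vary; odds ratios are undefined",
         call. = FALSE)
  }
  group <- stats::relevel(group, ref = reference)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ group, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  z <- stats::qnorm(0.975)
  separation <- sep_warn | se > 50 | abs(est) > 15
  out <- data.frame(
    group = sub("^group", "", names(est)),
    or = exp(est),
    ci_lower = exp(est - z * se),
    ci_upper = exp(est + z * se),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    separation = unname(separation),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$or[out$separation] <- NA_real_
  out$ci_lower[out$separation] <- NA_real_
  out$ci_upper[out$separation] <- NA_real_
  class(out) <- c("odds_result", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("Logistic odds ratios (reference: %s)\n",
              attr(x, "reference")))
  df <- as.data.frame(x)
  df$label <- ifelse(df$separation, "separation detected",
                     sprintf("%.3f (%.3f-%.3f), p = %.3g",
                             df$or, df$ci_lower, df$ci_upper, df$p_value))
  print(df[, c("group", "label")], row.names = FALSE)
  invisible(x)
}

#' Tabulate stenotic segments by group
#'
#' Counts, per group, the stenotic segments by segment identity, the
#' obstructive / non-obstructive severity split, and the composition
#' split (non-calcified-or-mixed vs calcified).  Both margins sum to the
#' group's total segment count by construction.
#'
#' @param lesions a lesion data frame with columns `patient_id`,
#'   `segment`, `stenosis_pct`, `composition`.
#' @param group group label per lesion row **or** a named vector of
#'   labels indexed by `patient_id`.
#' @param config a [ccta_config()].
#' @return A list of class `lesion_tabulation` with matrices `segments`
#'   (18 x k), `severity` (2 x k) and `composition` (2 x k) and the
#'   vector `totals`.
#' @export
tabulate_lesions <- function(lesions, group, config = ccta_config()) {
  stopifnot(is.data.frame(lesions))
  if (!is.null(names(group))) {
    group <- group[as.character(lesions$patient_id)]
  }
  group <- as.factor(group)
  stopifnot(length(group) == nrow(lesions) || nrow(lesions) == 0)
  seg <- factor(if (nrow(lesions)) canonical_segment(lesions$segment)
                else character(),
                levels = coronary_segments())
  segments <- table(seg, factor(group, levels = levels(group)))
  obstructive <- if (nrow(lesions)) {
    is_obstructive(lesions$stenosis_pct, config)
  } else logical()
  severity <- table(factor(ifelse(obstructive, "obstructive",
                                  "non_obstructive"),
                           levels = c("obstructive", "non_obstructive")),
                    factor(group, levels = levels(group)))
  calc <- if (nrow(lesions)) {
    canonical_composition(lesions$composition) == "calcified"
  } else logical()
  composition <- table(factor(ifelse(calc, "calcified",
                                     "non_calcified_or_mixed"),
                              levels = c("non_calcified_or_mixed",
                                         "calcified")),
                       factor(group, levels = levels(group)))
  structure(
    list(segments = unclass(segments),
         severity = unclass(severity),
         composition = unclass(composition),
         totals = colSums(segments)),
    class = "lesion_tabulation"
  )
}

#' @export
print.lesion_tabulation <- function(x, ...) {
  cat("Stenotic segment counts by group\n")
  seg <- x$segments
  rownames(seg) <- segment_printable(rownames(seg))
  print(seg)
  cat("Severity margin\n"); print(x$severity)
  cat("Composition margin\n"); print(x$composition)
  invisible(x)
}
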