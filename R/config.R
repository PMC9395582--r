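#' Analysis configuration
#'
#' Bundles every tunable threshold used across the scoring and comparison
#' pipeline so that one object can be passed through all stages.  The
#' defaults implement the conventional definitions: a stenosis of at least
#' `obstructive_cut` percent (50) is obstructive (grade 2), a stenosis
#' strictly above `severe_cut` percent (70) is severe (grade 3), and any
#' recorded plaque earns at least grade 1.  Score dichotomization uses
#' strict inequalities (SIS > 3, SSS > 5, CT-LeSc > 8.7).  UKPDS 10-year
#' fatal-CHD risk tiers are low < 7.5%, moderate 7.5-15% (both boundaries
#' inclusive), high > 15%.
#'
#' @param obstructive_cut percent; lowest stenosis counted as obstructive
#'   (grade 2).  Default 50.
#' @param severe_cut percent; stenosis strictly above this is severe
#'   (grade 3).  Default 70.
#' @param sis_threshold,sss_threshold,lesc_threshold strict dichotomization
#'   cut points for SIS, SSS and CT-LeSc.  Defaults 3, 5 and 8.7.
#' @param rounding `"full_precision"` (default) sums exact per-lesion
#'   partial CT-LeSc values; `"paper_2dp"` rounds each partial half-up to
#'   two decimals before summing, matching how the score is reported on
#'   clinical worksheets.
#' @param tier_low_max,tier_moderate_max risk-tier boundaries in percent:
#'   risk < `tier_low_max` is low, risk <= `tier_moderate_max` is moderate,
#'   anything above is high.  Defaults 7.5 and 15.
#' @param quantile_type percentile rule passed to [stats::quantile()] for
#'   interquartile ranges.  Default 7 (linear interpolation).
#' @param alpha two-sided significance level echoed in comparison reports.
#'   Default 0.05.
#' @param exact_max_n largest combined sample size at which the
#'   Mann-Whitney p-value is computed by full enumeration of group
#'   assignments rather than the normal approximation.  Default 10.
#'
#' @return An object of class `ccta_config` (a named list).
#' @examples
#' cfg <- ccta_config(rounding = "paper_2dp")
#' cfg$severe_cut
#' @export
ccta_config <- function(obstructive_cut = 50,
                        severe_cut = 70,
                        sis_threshold = 3,
                        sss_threshold = 5,
                        lesc_threshold = 8.7,
                        rounding = c("full_precision", "paper_2dp"),
                        tier_low_max = 7.5,
                        tier_moderate_max = 15,
                        quantile_type = 7,
                        alpha = 0.05,
                        exact_max_n = 10) {
  rounding <- match.arg(rounding)
  stopifnot(
    is.numeric(obstructive_cut), length(obstructive_cut) == 1L,
    is.numeric(severe_cut), length(severe_cut) == 1L,
    obstructive_cut > 0, severe_cut >= obstructive_cut, severe_cut <= 100,
    sis_threshold > 0, sss_threshold > 0, lesc_threshold > 0,
    tier_low_max > 0, tier_moderate_max >= tier_low_max,
    quantile_type %in% 1:9, alpha > 0, alpha < 1, exact_max_n >= 2
  )
  structure(
    list(
      obstructive_cut = obstructive_cut,
      severe_cut = severe_cut,
      sis_threshold = sis_threshold,
      sss_threshold = sss_threshold,
      lesc_threshold = lesc_threshold,
      rounding = rounding,
      tier_low_max = tier_low_max,
      tier_moderate_max = tier_moderate_max,
      quantile_type = quantile_type,
      alpha = alpha,
      exact_max_n = exact_max_n
    ),
    class = "ccta_config"
  )
}

#' @export
print.ccta_config <- function(x, ...) {
  cat("CCTA analysis configuration\n")
  cat(sprintf("  stenosis grades : 1 = <%g%%, 2 = %g-%g%%, 3 = >%g%%\n",
              x$obstructive_cut, x$obstructive_cut, x$severe_cut,
              x$severe_cut))
  cat(sprintf("  dichotomization : SIS > %g, SSS > %g, CT-LeSc > %g\n",
              x$sis_threshold, x$sss_threshold, x$lesc_threshold))
  cat(sprintf("  CT-LeSc rounding: %s\n", x$rounding))
  cat(sprintf("  risk tiers      : low < %g%%, moderate <= %g%%, high above\n",
              x$tier_low_max, x$tier_moderate_max))
  cat(sprintf("  alpha = %g, quantile type %d, exact MWU up to n = %d\n",
              x$alpha, x$quantile_type, as.integer(x$exact_max_n)))
  invisible(x)
}

# round half away from zero, the worksheet convention (base round() is
# round-half-even and would turn 0.615 into 0.61)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
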