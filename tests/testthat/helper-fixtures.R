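# Shared fixtures: random patient builders and an independent CT-LeSc
# oracle that re-reads the packaged weight table instead of going
# through segment_weight().

random_patient <- function(id = "p", max_lesions = 18) {
  dominance <- sample(dominance_levels(), 1)
  segs <- applicable_segments(dominance)
  n <- sample.int(min(max_lesions, length(segs)) + 1L, 1L) - 1L
  hit <- sample(segs, n)
  ccta_patient(id, dominance, data.frame(
    segment = hit,
    stenosis_pct = round(runif(n, 2, 100), 1),
    composition = sample(composition_levels(), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# brute-force CT-LeSc: independent table read (once), scalar loop
oracle_weight_tab <- read.csv(
  system.file("extdata", "ct_lesc_weights.csv", package = "cctascore"),
  stringsAsFactors = FALSE)

oracle_ct_lesc <- function(p, rounding = "full_precision",
                           tab = oracle_weight_tab) {
  total <- 0
  for (i in seq_len(nrow(p$lesions))) {
    row <- p$lesions[i, ]
    w <- tab$weight[tab$segment == row$segment &
                      tab$dominance == p$dominance]
    stopifnot(length(w) == 1, w != "na")
    part <- as.numeric(w) *
      (if (row$composition == "calcified") 1 else 1.5) *
      (if (row$stenosis_pct >= 50) 1 else 0.615)
    if (rounding == "paper_2dp") {
      part <- floor(part * 100 + 0.5 + 1e-9) / 100
    }
    total <- total + part
  }
  total
}

# the six-lesion worked-example patient, built inline (independent of
# the packaged fixture file)
worked_example <- function() {
  ccta_patient("fig_case", "right", data.frame(
    segment = c("left_main", "lad_proximal", "lad_mid", "diagonal_1",
                "lcx_proximal", "rca_proximal"),
    stenosis_pct = rep(30, 6),
    composition = c("mixed", "mixed", "mixed", "calcified", "calcified",
                    "calcified"),
    stringsAsFactors = FALSE
  ))
}

# exact two-sided Mann-Whitney p, written independently of the package:
# enumerate subsets of the pooled *values* and count pairwise wins/ties
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  sets <- combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
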