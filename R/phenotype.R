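#' Derived blood-pressure phenotypes and gestation-period means
#'
#' For each BP reading computes pulse pressure (PP = SBP - DBP) and mean
#' arterial pressure (MAP = DBP + PP/3), then averages SBP/DBP/MAP/PP within
#' the three gestation periods: early (< 20 weeks), middle (20 to < 34 weeks)
#' and late (>= 34 weeks).
#'
#' @param phenotypes a `pheno_table` (see [read_phenotypes()]).
#' @return list with `obs` (per-reading data.frame incl. `pp`, `map`,
#'   `period`) and `period_means` (one row per pair x period x trait, wide by
#'   trait, with `NA` where a period has no reading).
#' @export
derive_bp <- function(phenotypes) {
  bp <- phenotypes$bp
  if (nrow(bp) == 0L) stop("at least one BP observation is required")
  bp$pp <- bp$sbp - bp$dbp
  bp$map <- bp$dbp + bp$pp / 3
  stopifnot(all(bp$pp > 0))
  bp$period <- cut(bp$gestational_week, c(-Inf, 20, 34, Inf),
                   labels = c("early", "middle", "late"), right = FALSE)
  agg <- stats::aggregate(bp[c("sbp", "dbp", "map", "pp")],
                          by = list(pair_id = bp$pair_id, period = bp$period),
                          FUN = mean, drop = FALSE)
  list(obs = bp, period_means = agg)
}

#' Eligibility filter for the analysis cohort
#'
#' Removes records flagged with chronic hypertension or hypertensive disorder
#' of pregnancy (HDP), and deliveries before 34 completed weeks.
#'
#' @param phenotypes a `pheno_table`.
#' @return the filtered `pheno_table`.
#' @export
filter_eligible <- function(phenotypes) {
  p <- phenotypes$pairs
  keep <- p$hypertension_flag == "none" & p$gestational_age_at_delivery >= 34
  pairs <- p[keep, , drop = FALSE]
  bp <- phenotypes$bp[phenotypes$bp$pair_id %in% pairs$pair_id, , drop = FALSE]
  structure(list(pairs = pairs, bp = bp), class = "pheno_table")
}

# chart rows for (floored week, sex, parity); errors on missing strata
chart_lookup <- function(chart, week, sex, parity) {
  key <- paste(week, sex, parity)
  ckey <- paste(chart$week, chart$sex, chart$parity)
  idx <- match(key, ckey)
  if (anyNA(idx))
    stop("chart-coverage error: missing stratum ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  chart[idx, , drop = FALSE]
}

#' Reference-chart standardization of birth and placental weight
#'
#' Converts grams to z-scores against the chart stratum for the completed
#' (floored) gestational week, fetal sex and parity:
#' z = (weight - stratum mean) / stratum SD.
#'
#' @param phenotypes a `pheno_table`.
#' @param chart a `reference_chart`.
#' @return data.frame with `pair_id`, `bw_z`, `pw_z`.
#' @export
chart_adjust <- function(phenotypes, chart) {
  p <- phenotypes$pairs
  strat <- chart_lookup(chart, floor(p$gestational_age_at_delivery),
                        p$fetal_sex, p$parity)
  data.frame(pair_id = p$pair_id,
             bw_z = (p$birth_weight - strat$bw_mean) / strat$bw_sd,
             pw_z = (p$placental_weight - strat$pw_mean) / strat$pw_sd)
}

#' z-score transformation
#'
#' Centers and scales to unit sample variance (n-1 denominator). Constant
#' input is not an error: the result is flagged degenerate and returned as
#' all zeros so callers can decide.
#'
#' @param x numeric vector (NAs propagated).
#' @return list with `z` and logical `degenerate`.
#' @export
zscale <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    return(list(z = rep(0, length(x)), degenerate = TRUE))
  list(z = (x - mean(x, na.rm = TRUE)) / s, degenerate = FALSE)
}
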