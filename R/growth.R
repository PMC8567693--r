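#' Fit a smooth EFW growth curve for one fetus
#'
#' Fits a penalized cubic regression spline as a generalized additive model
#' (smoothness chosen by generalized cross-validation, basis dimension
#' capped at `k_max` -- ample for a sigmoidal weight curve and a guard
#' against GCV under-smoothing of sparse noisy series) to serial
#' estimated-fetal-weight observations, and evaluates weekly EFW on the
#' interior integer-week grid, from the ceiling of the first observed week
#' to the floor of the last (no extrapolation). Weekly velocity is the
#' first difference: `velocity[w] = efw[w] - efw[w-1]`, attributed to the
#' week the increment ends at.
#'
#' @param weeks numeric observation weeks (strictly increasing).
#' @param efw EFW observations (g).
#' @param min_obs minimum observations required (default 4).
#' @param min_span minimum observed span in weeks (default 6).
#' @param k_max maximum spline basis dimension (default 6).
#' @return object of class `growth_curve`: `weeks` (grid), `efw_weekly`,
#'   `velocity` (aligned to `weeks[-1]`), `edf` (effective degrees of
#'   freedom used).
#' @export
fit_growth_curve <- function(weeks, efw, min_obs = 4L, min_span = 6,
                             k_max = 6L) {
  if (length(weeks) < min_obs)
    stop("too few observations (", length(weeks), " < ", min_obs, ")")
  if (diff(range(weeks)) < min_span)
    stop("observation span below ", min_span, " weeks")
  if (any(diff(weeks) <= 0)) stop("weeks must be strictly increasing")
  k <- min(k_max, length(weeks))
  fit <- mgcv::gam(efw ~ s(weeks, k = k, bs = "cr"),
                   data = data.frame(weeks = weeks, efw = efw),
                   method = "GCV.Cp")
  grid <- seq(ceiling(min(weeks)), floor(max(weeks)))
  eff <- as.numeric(mgcv::predict.gam(fit, data.frame(weeks = grid)))
  structure(list(weeks = grid, efw_weekly = eff,
                 velocity = diff(eff), edf = sum(fit$edf) + 1),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Growth curve: weeks", min(x$weeks), "-", max(x$weeks),
      sprintf("(edf %.1f)\n", x$edf))
  invisible(x)
}

#' Fit growth curves for a cohort
#'
#' @param ultrasound long data.frame (`pair_id`, `gestational_week`, `efw`).
#' @param min_obs,min_span see [fit_growth_curve()]; fetuses failing either
#'   are excluded with the reason recorded.
#' @return list with `curves` (named list of `growth_curve`) and `excluded`
#'   (data.frame of pair_id + reason).
#' @export
fit_growth_curves <- function(ultrasound, min_obs = 4L, min_span = 6) {
  out <- list(); excl <- list()
  for (pid in unique(ultrasound$pair_id)) {
    d <- ultrasound[ultrasound$pair_id == pid, ]
    res <- tryCatch(
      fit_growth_curve(d$gestational_week, d$efw, min_obs, min_span),
      error = function(e) conditionMessage(e))
    if (is.character(res)) excl[[pid]] <- res else out[[pid]] <- res
  }
  list(curves = out,
       excluded = data.frame(pair_id = names(excl),
                             reason = unlist(excl, use.names = FALSE)))
}

#' Cross-sectional z-scored weekly velocity
#'
#' For each integer week, z-scores the weekly velocity across the fetuses
#' whose grid contains that week; fetuses lacking the week are missing, not
#' zero. Weeks with fewer than two fetuses are dropped; weeks with constant
#' velocity are flagged degenerate (z set to `NA`).
#'
#' @param curves named list of `growth_curve` objects.
#' @return long data.frame: `pair_id`, `week`, `velocity`, `velocity_z`,
#'   `degenerate`.
#' @export
weekly_znorm <- function(curves) {
  long <- do.call(rbind, lapply(names(curves), function(pid) {
    g <- curves[[pid]]
    data.frame(pair_id = pid, week = g$weeks[-1], velocity = g$velocity,
               stringsAsFactors = FALSE)
  }))
  res <- lapply(split(long, long$week), function(d) {
    if (nrow(d) < 2L) return(NULL)
    zs <- zscale(d$velocity)
    d$velocity_z <- if (zs$degenerate) NA_real_ else zs$z
    d$degenerate <- zs$degenerate
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tertile stratification of a score
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles; ties go to the lower
#' stratum. Strata are invariant under monotone transformation of the score.
#'
#' @param scores numeric vector (length >= 3, non-constant).
#' @return integer vector of strata in \{1, 2, 3\}.
#' @export
tertile_stratify <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 samples")
  if (stats::sd(scores) == 0) stop("constant scores cannot be stratified")
  q <- stats::quantile(scores, c(1, 2) / 3, names = FALSE)
  1L + (scores > q[1]) + (scores > q[2])
}

#' Per-week regressions of z-velocity on PGS tertile
#'
#' At each requested week, ordinary least squares of the cross-sectional
#' z-scored velocity on the tertile stratum entered as a numeric 1--3
#' covariate (the estimate is the change per stratum increase), flagged at
#' the Bonferroni threshold for the family of tests.
#'
#' @param velocity_z long data.frame from [weekly_znorm()].
#' @param strata named integer vector (pair_id -> stratum 1..3).
#' @param weeks weeks to test (default every 2 weeks, 22--36).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `week`, `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `significant`; the Bonferroni threshold is in
#'   `attr(, "threshold")`.
#' @export
velocity_regressions <- function(velocity_z, strata,
                                 weeks = seq(22, 36, by = 2),
                                 alpha = 0.05) {
  thr <- bonferroni(alpha, length(weeks))
  rows <- lapply(weeks, function(w) {
    d <- velocity_z[velocity_z$week == w & !is.na(velocity_z$velocity_z), ]
    d$stratum <- strata[d$pair_id]
    d <- d[!is.na(d$stratum), ]
    if (nrow(d) < 3L || stats::sd(d$stratum) == 0)
      return(data.frame(week = w, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n = nrow(d), significant = NA))
    fit <- stats::lm(velocity_z ~ stratum, data = d)
    sm <- summary(fit)$coefficients["stratum", ]
    ci <- stats::confint(fit)["stratum", ]
    data.frame(week = w, estimate = sm[["Estimate"]], ci_low = ci[[1]],
               ci_high = ci[[2]], p_value = sm[["Pr(>|t|)"]], n = nrow(d),
               significant = sm[["Pr(>|t|)"]] < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
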