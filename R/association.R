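#' Standardized regression with confounders
#'
#' Ordinary least squares of a z-scaled outcome on a z-scaled predictor and
#' optional z-scaled confounders (complete cases). For a simple regression
#' the standardized estimate equals the Pearson correlation.
#'
#' @param data data.frame.
#' @param outcome,predictor column names.
#' @param confounders character vector of column names.
#' @param family_size Bonferroni family size for the adjusted p-value.
#' @return data.frame (one row): `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `p_bonferroni`, `adjusted_r2`, `n`.
#' @export
regress <- function(data, outcome, predictor, confounders = character(0),
                    family_size = 1L) {
  vars <- c(outcome, predictor, confounders)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  d <- stats::na.omit(data[vars])
  if (nrow(d) < length(vars) + 2L)
    stop("too few complete cases (n = ", nrow(d), ")")
  for (v in vars) {
    zs <- zscale(d[[v]])
    if (zs$degenerate) stop("constant variable: ", v)
    d[[v]] <- zs$z
  }
  f <- stats::as.formula(paste(bq(outcome), "~",
                               paste(bq(c(predictor, confounders)),
                                     collapse = " + ")))
  fit <- stats::lm(f, data = d)
  sm <- summary(fit)
  co <- sm$coefficients[bq(predictor), ]
  ci <- stats::confint(fit)[bq(predictor), ]
  data.frame(estimate = co[["Estimate"]], ci_low = ci[[1]], ci_high = ci[[2]],
             p_value = co[["Pr(>|t|)"]],
             p_bonferroni = min(1, co[["Pr(>|t|)"]] * family_size),
             adjusted_r2 = sm$adj.r.squared, n = nrow(d))
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Linear versus quadratic model choice by AIC
#'
#' Fits `y ~ x` and `y ~ x + x^2` and prefers the lower-AIC model; residual
#' normality (Shapiro-Wilk on the preferred model's residuals, n <= 5000)
#' is reported as a diagnostic.
#'
#' @param y,x numeric vectors (n >= 10).
#' @return list: `preferred` (`"linear"`/`"quadratic"`), `aic_linear`,
#'   `aic_quadratic`, `shapiro_p`, `fit_linear`, `fit_quadratic`.
#' @export
compare_linear_quadratic <- function(y, x) {
  if (length(y) < 10L) stop("need n >= 10")
  if (stats::sd(x) == 0) stop("constant predictor")
  d <- data.frame(y = y, x = x)
  f1 <- stats::lm(y ~ x, data = d)
  f2 <- stats::lm(y ~ x + I(x^2), data = d)
  a1 <- stats::AIC(f1); a2 <- stats::AIC(f2)
  pref <- if (a2 < a1) "quadratic" else "linear"
  res <- stats::resid(if (pref == "linear") f1 else f2)
  sw <- if (length(res) >= 3 && length(res) <= 5000)
    stats::shapiro.test(res)$p.value else NA_real_
  list(preferred = pref, aic_linear = a1, aic_quadratic = a2,
       shapiro_p = sw, fit_linear = f1, fit_quadratic = f2)
}

# power of the overall F test of a linear regression with u numerator df,
# n observations and effect size f2, using ncp = f2 * (u + v + 1)
regression_power <- function(n, u, f2, alpha) {
  v <- n - u - 1
  if (v < 1) return(0)
  stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = f2 * (u + v + 1),
            lower.tail = FALSE)
}

#' Minimum sample size for a linear regression F test
#'
#' Smallest n such that the noncentral-F test of the regression (numerator
#' df `u`, denominator df `n - u - 1`, noncentrality `f2 * (u + (n-u-1) +
#' 1)`) attains the target power at level alpha. The effect size f2 is
#' R2/(1-R2) by default; `f2_convention = "r2"` passes R2 directly, since a
#' stated "R-squared" specification can be fed to power software either way.
#'
#' @param alpha significance level.
#' @param power target power.
#' @param r2 coefficient of determination of the regression.
#' @param u numerator degrees of freedom (number of tested predictors).
#' @param f2_convention `"ratio"` (f2 = r2/(1-r2), default) or `"r2"`.
#' @return integer minimal n, with attributes `achieved_power` and `f2`.
#' @export
required_sample_size <- function(alpha = 0.05, power = 0.80, r2 = 0.15,
                                 u = 1L, f2_convention = c("ratio", "r2")) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 ||
      r2 <= 0 || r2 >= 1)
    stop("alpha, power and r2 must lie in (0, 1)")
  f2_convention <- match.arg(f2_convention)
  f2 <- if (f2_convention == "ratio") r2 / (1 - r2) else r2
  lo <- u + 2L
  hi <- lo
  while (regression_power(hi, u, f2, alpha) < power) {
    hi <- hi * 2L
    if (hi > 1e7) stop("infeasible specification")
  }
  while (lo < hi) {               # bisection on the monotone power curve
    mid <- (lo + hi) %/% 2L
    if (regression_power(mid, u, f2, alpha) >= power) hi <- mid else lo <- mid + 1L
  }
  structure(lo, achieved_power = regression_power(lo, u, f2, alpha), f2 = f2)
}
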