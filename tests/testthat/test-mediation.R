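test_that("ACME + ADE equals the total effect exactly and CIs are sane", {
  d <- simulate_sem(200, seed = 201)
  fit <- mediate_linear(d, "G_z", "M_z", "Y_z", "B_z", n_sims = 500,
                        seed = 1)
  est <- fit$estimates
  expect_equal(est[["acme"]] + est[["ade"]], est[["total"]],
               tolerance = 1e-9)
  for (eff in c("acme", "ade", "total")) {
    expect_gte(est[[eff]], fit$ci[eff, 1])
    expect_lte(est[[eff]], fit$ci[eff, 2])
  }
  # product of coefficients from independent lm fits is the same number
  a_hat <- coef(lm(M_z ~ G_z + B_z, data = d))[["G_z"]]
  b_hat <- coef(lm(Y_z ~ G_z + M_z + B_z, data = d))[["M_z"]]
  expect_equal(est[["acme"]], a_hat * b_hat, tolerance = 1e-12)
})

test_that("the fit is reproducible and guards its preconditions", {
  d <- simulate_sem(120, seed = 202)
  f1 <- mediate_linear(d, "G_z", "M_z", "Y_z", n_sims = 300, seed = 9)
  f2 <- mediate_linear(d, "G_z", "M_z", "Y_z", n_sims = 300, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_error(mediate_linear(d, "G_z", "M_z", "Y_z", n_sims = 300),
               "seed")
  expect_warning(mediate_linear(d, "G_z", "M_z", "Y_z", n_sims = 50,
                                seed = 1), "n_sims")
  d$G2 <- d$G_z
  expect_error(mediate_linear(d, "G_z", "M_z", "Y_z", "G2", n_sims = 300,
                              seed = 1), "collinear")
})

test_that("null-path ACME intervals cover zero at the nominal rate", {
  cover <- vapply(1:200, function(k) {
    d <- simulate_sem(500, a = 0, seed = 400 + k)
    f <- mediate_linear(d, "G_z", "M_z", "Y_z", "B_z", n_sims = 300,
                        seed = k)
    f$ci["acme", 1] <= 0 && f$ci["acme", 2] >= 0
  }, TRUE)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("calibrated paths recover the generating ACME at n = 93", {
  f <- mediate_linear(simulate_sem(93, seed = 205), "G_z", "M_z", "Y_z",
                      "B_z", n_sims = 1000, seed = 5)
  mc_se <- sd(f$draws[, "acme"])
  expect_lt(abs(f$estimates[["acme"]] - (-0.396 * 0.661)), 2 * mc_se)
})

test_that("proportion mediated is recovered by the ratio of means", {
  res <- t(vapply(1:200, function(k) {
    d <- simulate_sem(93, seed = 600 + k)
    f <- mediate_linear(d, "G_z", "M_z", "Y_z", "B_z", n_sims = 200,
                        seed = k)
    f$estimates[c("acme", "total")]
  }, c(acme = 0, total = 0)))
  prop <- mean(res[, "acme"]) / mean(res[, "total"])
  truth <- (-0.396 * 0.661) / (-0.396 * 0.661 - 0.049)
  expect_lt(abs(prop - truth), 0.05)
})

test_that("sensitivity curve anchors at rho = 0 and is monotone", {
  d <- simulate_sem(150, seed = 207)
  fit <- mediate_linear(d, "G_z", "M_z", "Y_z", "B_z", n_sims = 300,
                        seed = 2)
  sens <- sensitivity(fit)
  expect_equal(sens$acme[sens$rho == 0], fit$estimates[["acme"]],
               tolerance = 1e-9)
  # monotone on a grid refined 100-fold (numerical oracle)
  fine <- sensitivity(fit, rho_grid = seq(-0.9, 0.9, by = 0.001))
  expect_true(all(diff(fine$acme) > 0) || all(diff(fine$acme) < 0))
  # coarse grid is a subset of the refined curve
  sub <- fine$acme[match(round(sens$rho, 3), round(fine$rho, 3))]
  expect_equal(sens$acme, sub, tolerance = 1e-12)
  # the zero crossing sits at the residual correlation rho-tilde
  rt <- attr(sens, "rho_tilde")
  at_rt <- sensitivity(fit, rho_grid = rt)$acme
  expect_lt(abs(at_rt), 1e-9)
  expect_error(sensitivity(fit, rho_grid = c(0, 1)), "rho")
})

test_that("a calibrated negative ACME stays negative below rho-tilde", {
  d <- simulate_sem(93, seed = 208)
  fit <- mediate_linear(d, "G_z", "M_z", "Y_z", "B_z", n_sims = 300,
                        seed = 3)
  sens <- sensitivity(fit)
  rt <- attr(sens, "rho_tilde")
  expect_gt(rt, 0.4)      # outcome and mediator residuals strongly correlated
  expect_true(all(sens$acme[sens$rho < rt - 0.05] < 0))
})

test_that("the battery is stable across pleiotropy-style exposure variants", {
  d <- simulate_sem(300, seed = 209)
  # jitter emulates removing a handful of near-null variants from the score
  exposures <- list(full = d$G_z,
                    excl_a = d$G_z + rnorm(300, 0, 0.02),
                    excl_b = d$G_z + rnorm(300, 0, 0.02))
  bat <- mediation_battery(d, exposures, "M_z", "Y_z", "B_z",
                           n_sims = 300, seed = 4)
  expect_equal(nrow(bat), 3L)
  expect_lt(max(bat$acme) - min(bat$acme), 0.05)
  # single exposure gives a single row
  bat1 <- mediation_battery(d, exposures["full"], "M_z", "Y_z", "B_z",
                            n_sims = 200, seed = 4)
  expect_equal(nrow(bat1), 1L)
})

test_that("mediated and unmediated genetic scores separate in the battery", {
  set.seed(210)
  n <- 400
  G <- rnorm(n)                  # effect routed through the mediator
  D <- rnorm(n)                  # direct-only effect (no mediator path)
  M <- -0.4 * G + rnorm(n, 0, sqrt(1 - 0.16))
  Y <- 0.66 * M - 0.05 * G - 0.3 * D + rnorm(n, 0, 0.6)
  d <- data.frame(M_z = zscale(M)$z, Y_z = zscale(Y)$z)
  bat <- mediation_battery(d, list(vasc = G, unlikely = D), "M_z", "Y_z",
                           n_sims = 300, seed = 6)
  expect_gt(bat$prop_mediated[bat$exposure == "vasc"],
            bat$prop_mediated[bat$exposure == "unlikely"])
  expect_gt(abs(bat$acme[bat$exposure == "vasc"]),
            abs(bat$acme[bat$exposure == "unlikely"]))
})

test_that("methods on the fit object behave", {
  d <- simulate_sem(150, seed = 211)
  fit <- mediate_linear(d, "G_z", "M_z", "Y_z", n_sims = 300, seed = 8)
  expect_named(coef(fit), c("acme", "ade", "total", "prop_mediated"))
  ci <- confint(fit, level = 0.9)
  expect_true(ci["acme", 1] < coef(fit)[["acme"]])
  expect_output(print(fit), "quasi-Bayesian")
  expect_output(print(summary(fit)), "acme")
})
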