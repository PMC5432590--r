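ww <- list(alpha = 4.32, plc50 = -1.31)

test_that("predict_plc follows the sigmoid: midpoint, asymptotes, monotonicity", {
  expect_equal(predict_plc(ww, ww$plc50), 50)
  expect_equal(predict_plc(ww, 1e6), 0)
  expect_equal(predict_plc(ww, -1e6), 100)
  # closed-form inversion: psi placed at the 12%-loss point predicts 12
  psi12 <- ww$plc50 + log(88 / 12) / ww$alpha
  expect_equal(predict_plc(ww, psi12), 12)
  psi <- seq(-3, 0, by = 0.05)
  expect_true(all(diff(predict_plc(ww, psi)) < 0))  # increases as psi drops
})

test_that("psi_at_plc is the closed-form inverse, symmetric about the midpoint", {
  expect_equal(psi_at_plc(ww, 50), ww$plc50)
  expect_equal(psi_at_plc(ww, 88), -1.31 - log(88 / 12) / 4.32)
  # psi12 and psi88 are mirror images about plc50
  expect_equal(psi_at_plc(ww, 12) - ww$plc50, ww$plc50 - psi_at_plc(ww, 88))
  # identity with predict_plc across the whole open interval
  for (lev in c(0.5, 5, 12, 37, 50, 63, 88, 99.5)) {
    expect_equal(predict_plc(ww, psi_at_plc(ww, lev)), lev, tolerance = 1e-10)
  }
  # cross-check the closed form by root finding on the forward curve
  root <- uniroot(function(p) predict_plc(ww, p) - 88, c(-5, 0), tol = 1e-12)$root
  expect_equal(psi_at_plc(ww, 88), root, tolerance = 1e-8)
  expect_error(psi_at_plc(ww, 0), "level")
  expect_error(psi_at_plc(ww, 100), "level")
})

test_that("linearize transforms interior PLC and counts boundary exclusions", {
  obs <- data.frame(psi_stem = c(-1, -1, -1, -1),
                    plc = c(50, 12, 0, 100))
  lin <- linearize(obs)
  expect_equal(nrow(lin), 2)
  expect_equal(attr(lin, "n_excluded"), 2)
  expect_equal(lin$y, c(0, log(88 / 12)))
})

test_that("fit_vc recovers generating parameters exactly from noiseless data", {
  d <- simulate_vc(4.32, -1.31, n = 20, noise_sd = 0, seed = 11)
  f <- fit_vc(d, n_bootstrap = 0)
  expect_equal(f$alpha, 4.32, tolerance = 1e-6)
  expect_equal(f$plc50, -1.31, tolerance = 1e-6)
  expect_equal(f$slope_at_p50, 25 * f$alpha)
  expect_equal(f$psi12, psi_at_plc(f, 12))
  expect_equal(f$psi88, psi_at_plc(f, 88))
  expect_true(f$psi12 > f$plc50 && f$plc50 > f$psi88)
  expect_lt(f$residual_sd, 1e-6)
})

test_that("fit_vc flags degenerate data and rejects unusable input", {
  flat <- data.frame(psi_stem = seq(-2, -0.5, length.out = 8), plc = rep(50, 8))
  expect_warning(f <- fit_vc(flat, n_bootstrap = 0), "one side of 50")
  expect_true(f$degenerate)
  expect_lt(f$alpha, 0.1)
  expect_true(f$plc50 >= -2 && f$plc50 <= -0.5)  # interior to the psi range
  expect_error(fit_vc(data.frame(psi_stem = -1, plc = 10), n_bootstrap = 0),
               "at least 4")
  expect_error(
    fit_vc(data.frame(psi_stem = c(-1, -1.2, -1.4, -1.6),
                      plc = c(5, 120, 50, 60)), n_bootstrap = 0),
    "\\[0, 100\\]")
})

test_that("noisy recovery lands near truth with bootstrap CI covering it", {
  d <- simulate_vc(4.32, -1.31, n = 36, noise_sd = 5, seed = 2)
  f <- fit_vc(d, n_bootstrap = 200, seed = 3)
  expect_true(abs(f$plc50 - (-1.31)) < 0.2)
  expect_true(f$ci[1, "plc50"] <= -1.31 && -1.31 <= f$ci[2, "plc50"])
  # same data, same seed: identical fit and intervals
  f2 <- fit_vc(d, n_bootstrap = 200, seed = 3)
  expect_identical(f$ci, f2$ci)
})

test_that("linearized back-solve agrees with the nonlinear fit on noiseless data", {
  d <- simulate_vc(4.12, -1.18, n = 24, noise_sd = 0, seed = 7)
  f <- fit_vc(d, n_bootstrap = 0)
  lin <- linearize(d)
  cf <- coef(lm(y ~ psi_stem, data = lin))
  alpha_lin <- unname(cf["psi_stem"])
  plc50_lin <- -unname(cf["(Intercept)"]) / alpha_lin
  expect_equal(alpha_lin, f$alpha, tolerance = 1e-6)
  expect_equal(plc50_lin, f$plc50, tolerance = 1e-6)
})

test_that("compare_treatments back-solves per-treatment curves and is label-invariant", {
  a <- simulate_vc(4.32, -1.31, n = 20, noise_sd = 0, seed = 5, treatment = "A")
  b <- a; b$treatment <- "B"
  # identical data under two labels: identical coefficients, no treatment signal
  cmp <- compare_treatments(rbind(a, b))
  expect_equal(cmp$coefficients$alpha[1], cmp$coefficients$alpha[2])
  expect_equal(cmp$coefficients$plc50[1], cmp$coefficients$plc50[2])
  expect_equal(cmp$coefficients$plc50[1], -1.31, tolerance = 1e-6)
  expect_error(compare_treatments(a), "at least 2 treatments")
})

test_that("compare_treatments errors on rank-deficient designs, naming the terms", {
  a <- simulate_vc(4.32, -1.31, n = 12, noise_sd = 2, seed = 8, treatment = "A")
  b <- a
  b$treatment <- "B"
  b$psi_stem <- -1  # single psi value: interaction aliased with main effect
  b$plc <- 40 + rnorm(12)
  expect_error(compare_treatments(rbind(a, b)), "collinear")
})

test_that("treatment difference in plc50 is detected by the joint test", {
  set.seed(31)
  a <- simulate_vc(4.32, -1.31, n = 30, noise_sd = 5, treatment = "A")
  b <- simulate_vc(4.32, -1.01, n = 30, noise_sd = 5, treatment = "B")
  cmp <- compare_treatments(rbind(a, b))
  expect_lt(cmp$joint_test$p_value, 0.05)
  expect_equal(nrow(cmp$coefficients), 2)
})

test_that("free-asymptote fit recovers a sub-100 maximum", {
  psi <- seq(-2.5, -0.3, length.out = 25)
  d <- data.frame(psi_stem = psi, plc = 90 / (1 + exp(4 * (psi + 1.2))))
  f <- fit_vc(d, n_bootstrap = 0, free_max = TRUE)
  expect_equal(f$plc_max, 90, tolerance = 1e-4)
  expect_equal(f$plc50, -1.2, tolerance = 1e-4)
  expect_equal(f$slope_at_p50, f$plc_max * f$alpha / 4)
})

test_that("bootstrap intervals are approximately calibrated for PLC50", {
  # 200 seeded recovery replicates; percentile CIs from 499 resamples each.
  # Nominal 95% coverage, accepted within +/- 5 points.
  covered <- vapply(1:200, function(s) {
    d <- simulate_vc(4.32, -1.31, n = 36, noise_sd = 5, seed = 5000 + s)
    f <- fit_vc(d, n_bootstrap = 499, seed = 6000 + s)
    f$ci[1, "plc50"] <= -1.31 && -1.31 <= f$ci[2, "plc50"]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})
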