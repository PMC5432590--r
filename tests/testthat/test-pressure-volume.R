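test_that("compute_rwc maps weights to relative water content", {
  obs <- data.frame(fresh_weight = c(2.0, 1.25, 0.5001),
                    psi_leaf = c(0, -1, -3))
  cv <- pv_curve(obs, turgid_weight = 2.0, dry_weight = 0.5)
  rwc <- compute_rwc(cv)
  expect_equal(as.numeric(rwc)[1:2], c(100, 50))
  expect_lt(as.numeric(rwc)[3], 0.01)
  expect_error(pv_curve(obs, turgid_weight = 0.5, dry_weight = 0.5),
               "turgid_weight > dry_weight")
  # over-turgid weights are clipped with a flag, not rejected
  obs2 <- data.frame(fresh_weight = c(2.1, 1.8, 1.5), psi_leaf = c(0, -1, -2))
  expect_warning(cv2 <- pv_curve(obs2, 2.0, 0.5), "above turgid")
  expect_warning(r2 <- compute_rwc(cv2), "clipped")
  expect_equal(as.numeric(r2)[1], 100)
  expect_true(attr(r2, "clipped")[1])
})

test_that("fit_pv recovers forward-model parameters from noiseless curves", {
  cv <- simulate_pv(pi100 = -1.0, epsilon = 6.0, apoplastic_fraction = 0.2,
                    noise_rel = 0)
  f <- fit_pv(cv)
  expect_equal(f$pi100, -1.0, tolerance = 0.01)
  expect_equal(f$epsilon, 6.0, tolerance = 0.01)
  expect_equal(f$apoplastic_fraction, 0.2, tolerance = 0.01)
  expect_true(f$psi_tlp <= f$pi100)
  expect_lt(f$rwc_tlp, 100)
})

test_that("recovered turgor loss point matches the analytic value at zero noise", {
  truths <- expand.grid(pi100 = c(-1.5, -1.1, -0.8), epsilon = c(4, 7.17, 10))
  for (i in seq_len(nrow(truths))) {
    p <- truths$pi100[i]; e <- truths$epsilon[i]
    # grid spanning well past the analytic TLP, ~0.4 RWC-point resolution
    rwc_tlp <- 100 * (1 + p / e)
    rwc_min <- rwc_tlp - 0.6 * (100 - rwc_tlp)
    n <- max(24, ceiling((100 - rwc_min) / 0.4))
    cv <- simulate_pv(p, e, apoplastic_fraction = 0, n = n, rwc_min = rwc_min,
                      noise_rel = 0)
    f <- fit_pv(cv)
    analytic <- p * e / (e + p)
    expect_lt(abs(f$psi_tlp - analytic), 0.02)
    expect_equal(f$pi100, p, tolerance = 0.01)
    expect_equal(f$epsilon, e, tolerance = 0.05)
  }
})

test_that("psi_tlp responds monotonically to the osmotic generating parameter", {
  tlps <- sapply(c(-0.8, -1.0, -1.2, -1.4), function(p) {
    fit_pv(simulate_pv(p, 7, 0, n = 20, rwc_min = 65, noise_rel = 0))$psi_tlp
  })
  expect_true(all(diff(tlps) < 0))
})

test_that("fit_pv is invariant to uniform rescaling of the weights", {
  cv <- simulate_pv(-1.1, 7.17, 0.1, noise_rel = 0.005, seed = 21)
  scaled <- pv_curve(
    data.frame(fresh_weight = 3.7 * cv$observations$fresh_weight,
               psi_leaf = cv$observations$psi_leaf),
    turgid_weight = 3.7 * cv$turgid_weight,
    dry_weight = 3.7 * cv$dry_weight)
  f1 <- fit_pv(cv); f2 <- fit_pv(scaled)
  expect_equal(f1$pi100, f2$pi100)
  expect_equal(f1$epsilon, f2$epsilon)
  expect_equal(f1$psi_tlp, f2$psi_tlp)
  expect_equal(f1$rwc_tlp, f2$rwc_tlp)
})

test_that("a curve lying on a single osmotic line has its TLP at the wettest point", {
  # pure osmotic behaviour (no turgor phase anywhere): y = -1/psi linear in x
  rwc <- seq(98, 70, length.out = 10)
  psi <- -1.0 / (rwc / 100)          # pi100 = -1, af = 0, always past turgor
  fresh <- 0.5 + 1.5 * rwc / 100
  cv <- pv_curve(data.frame(fresh_weight = fresh, psi_leaf = psi),
                 turgid_weight = 2.0, dry_weight = 0.5)
  expect_warning(f <- fit_pv(cv), "turgor phase")
  expect_equal(f$n_points_osmotic_line, 10)   # the entire curve
  expect_equal(f$rwc_tlp, 98)                  # wettest point
  expect_true(is.na(f$epsilon))
  expect_equal(f$pi100, -1.0, tolerance = 1e-6)
})

test_that("fit_pv rejects curves that are too short", {
  cv <- simulate_pv(-1.1, 7, 0, n = 15, noise_rel = 0)
  cv$observations <- cv$observations[1:6, ]
  expect_error(fit_pv(cv), "at least 8")
})

test_that("pv_parameter_table aggregates per-treatment means and SEs", {
  fits <- lapply(1:6, function(i) {
    fit_pv(simulate_pv(-1.1, 7.17, 0, n = 15, noise_rel = 0.01, seed = 100 + i,
                       treatment = if (i <= 3) "SD" else "WW"))
  })
  tab <- pv_parameter_table(fits)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$treatment), c("SD", "WW"))
  expect_equal(tab$n, c(3, 3))
  expect_true(all(is.finite(tab$psi_tlp_mean)))
  expect_true(all(is.finite(tab$psi_tlp_se)))
})

test_that("long-format reader reconstructs per-leaf curves", {
  f <- withr::local_tempfile(fileext = ".csv")
  cv <- simulate_pv(-1.1, 7, 0, noise_rel = 0)
  d <- data.frame(leaf_id = "L1", cv$observations,
                  turgid_weight = cv$turgid_weight,
                  dry_weight = cv$dry_weight, treatment = "SD")
  write.csv(rbind(d, within(d, leaf_id <- "L2")), f, row.names = FALSE)
  curves <- read_pv_curves(f)
  expect_length(curves, 2)
  expect_s3_class(curves$L1, "pv_curve")
  expect_equal(curves$L2$treatment, "SD")
  expect_equal(fit_pv(curves$L1)$pi100, -1.1, tolerance = 0.01)
})
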