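test_that("equivalent_diameter inverts the circle-area formula", {
  expect_equal(equivalent_diameter(pi / 4), 1)
  expect_equal(equivalent_diameter(100 * pi), 20)
  set.seed(1)
  a <- runif(50, 10, 2000)
  expect_equal(pi * (equivalent_diameter(a) / 2)^2, a)
  expect_error(equivalent_diameter(0), "positive")
  expect_error(equivalent_diameter(-3), "positive")
})

test_that("theoretical_conductivity tracks the unit-annotated oracle", {
  # single 20-um vessel against the spelled-out hand computation
  expect_equal(theoretical_conductivity(20),
               (pi * 1000 / (128 * 1e-9)) * (2e-5)^4 / 0.018015 * 1000)
  # random vessel sets, elementwise unit-tracked oracle, 1e-12 relative
  set.seed(7)
  for (i in 1:20) {
    d <- exp(rnorm(sample(1:50, 1), log(18), 0.4))
    expect_equal(theoretical_conductivity(d), oracle_kt(d),
                 tolerance = 1e-12)
    expect_equal(theoretical_conductivity(d, extrapolate_half = TRUE),
                 oracle_kt(d, extrapolate_half = TRUE), tolerance = 1e-12)
  }
})

test_that("conductivity follows the fourth-power scaling law", {
  d <- c(12, 18, 25, 31)
  expect_equal(theoretical_conductivity(2 * d),
               16 * theoretical_conductivity(d))
  expect_equal(theoretical_conductivity(d, extrapolate_half = TRUE),
               2 * theoretical_conductivity(d))
  expect_warning(k0 <- theoretical_conductivity(numeric(0)), "empty")
  expect_equal(k0, 0)
  # strictly increasing under addition of any vessel
  expect_gt(theoretical_conductivity(c(d, 5)), theoretical_conductivity(d))
})

test_that("specific_conductivity normalizes by leaf area in m^2", {
  expect_equal(specific_conductivity(0, 120), 0)
  expect_equal(specific_conductivity(1, 1e4), 1)   # 1e4 cm^2 = 1 m^2
  expect_equal(specific_conductivity(3, 60), 2 * specific_conductivity(3, 120))
  expect_error(specific_conductivity(1, 0), "leaf_area")
})

test_that("vessel_class_distribution partitions counts and d^4 contributions", {
  one <- vessel_class_distribution(c(17, 18, 19))
  expect_equal(one$freq_pct[one$class == "15-20"], 100)
  expect_equal(one$kt_pct[one$class == "15-20"], 100)
  two <- vessel_class_distribution(c(10, 20))
  expect_equal(two$freq_pct[two$class %in% c("10-15", "20-25")], c(50, 50))
  expect_equal(two$kt_pct[two$class == "10-15"], 100 / 17)
  expect_equal(two$kt_pct[two$class == "20-25"], 1600 / 17)
  set.seed(3)
  d <- exp(rnorm(200, log(19), 0.35))
  v <- vessel_class_distribution(d)
  expect_equal(sum(v$freq_pct), 100, tolerance = 1e-9)
  expect_equal(sum(v$kt_pct), 100, tolerance = 1e-9)
  expect_equal(sum(v$count), 200)
  expect_error(vessel_class_distribution(d, bin_edges = c(10, 10, 20)),
               "strictly increasing")
})

test_that("per-class contributions re-aggregate to the total conductivity", {
  set.seed(11)
  d <- exp(rnorm(120, log(20), 0.3))
  v <- vessel_class_distribution(d)
  kt <- theoretical_conductivity(d)
  expect_equal(sum(v$kt_pct / 100 * kt), kt, tolerance = 1e-12)
})

test_that("section_conductivity reports quantities consistent with its inputs", {
  ves <- simulate_vessels(mean_diameter = 20, n = 150, seed = 9)
  sec <- petiole_section(ves, petiole_area = 5.5, leaf_area = 160,
                         n_bundles = 25, half_section = TRUE,
                         section_id = "S1", treatment = "WW")
  out <- section_conductivity(sec)
  expect_equal(out$n_vessels, 300)                       # extrapolated
  expect_equal(out$mean_diameter_um, mean(ves$diameter_um))
  expect_equal(out$total_vessel_area_mm2,
               2 * sum(ves$lumen_area_um2) * 1e-6)
  expect_equal(out$k_t, theoretical_conductivity(ves$diameter_um,
                                                 extrapolate_half = TRUE))
  expect_equal(out$k_ts, out$k_t / (160 * 1e-4))
})

test_that("vessel and section CSVs round-trip through the reader", {
  vf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  ves <- simulate_vessels(mean_diameter = 19, n = 40, seed = 4)
  write.csv(data.frame(section_id = "P1",
                       lumen_area_um2 = ves$lumen_area_um2), vf,
            row.names = FALSE)
  write.csv(data.frame(section_id = "P1", leaf_area_cm2 = 150,
                       petiole_area_mm2 = 5.0, half_section = TRUE,
                       treatment = "TD"), sf, row.names = FALSE)
  secs <- read_petiole_sections(vf, sf)
  expect_length(secs, 1)
  # diameters recovered from areas via the equivalent-circle transform
  expect_equal(sort(secs$P1$vessels$diameter_um), sort(ves$diameter_um))
  expect_true(secs$P1$half_section)
  expect_equal(section_conductivity(secs$P1)$n_vessels, 80)
})
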