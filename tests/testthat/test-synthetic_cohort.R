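test_that("synthetic vessels match their requested geometry", {
  sv <- synthetic_vessel(40, 2, taper = 0, bend_curvature = 0)
  expect_true(all(sv$vessel$radius == 2))
  expect_equal(sv$vessel$xyz[, 2], rep(0, length(sv$vessel$s)))
  expect_equal(vessel_length(sv$vessel), 40)

  curved <- synthetic_vessel(40, 1.5, bend_curvature = 0.05, ds = 0.2)
  k <- curvature_at(curved$vessel, seq(10, 30, 5))
  expect_true(all(abs(k$kappa - 0.05) < 0.001))

  expect_error(synthetic_vessel(40, 15, bend_curvature = 0.1),
               "infeasible")
  expect_error(synthetic_vessel(-5, 2), "infeasible")
  expect_s3_class(sv$region, "aneurysm_region")
  expect_s3_class(sv$morphology, "aneurysm_morphology")
  expect_lte(sv$morphology$neck_min, sv$morphology$neck_max)
})

test_that("generation is seed-deterministic", {
  a <- generate_cohort(n = 30, seed = 42)
  b <- generate_cohort(n = 30, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(n = 30, seed = 43)
  expect_false(identical(a$porosity_mean, c$porosity_mean))
  sv1 <- synthetic_vessel(30, 1.8, seed = 7)
  sv2 <- synthetic_vessel(30, 1.8, seed = 7)
  expect_identical(sv1, sv2)
})

test_that("generated cohorts satisfy the schema invariants", {
  tab <- generate_cohort(n = 64, seed = 1)
  expect_silent(validate_cohort(tab))
  expect_true(all(tab$fu_months >= 6 & tab$fu_months <= 12))
  occ <- tab$occluded == 1
  expect_true(all(tab$tto_months[occ] > 0))
  expect_true(all(tab$tto_months[occ] <= tab$fu_months[occ]))
  expect_true(all(is.na(tab$tto_months[!occ])))
  expect_true(all(tab$brand_label %in% names(fd_presets())))
  # mesh summaries within physical ranges
  expect_true(all(tab$porosity_mean > 0 & tab$porosity_mean < 1))
  expect_true(all(tab$expansion_mean <= 100))
  # truth sidecar carries the generating model
  tr <- attr(tab, "truth")
  expect_named(tr$logit_coef)
  expect_named(tr$tto_coef)
  expect_gt(tr$tto_sigma, 0)
  expect_length(tr$eta_logit, 64)
})

test_that("the default truth reproduces the anchored occlusion rate", {
  # occluded counts should scatter around 51/64
  counts <- vapply(1:6, function(s) sum(generate_cohort(n = 64, seed = s)$occluded),
                   numeric(1))
  p <- 51 / 64
  expect_true(all(abs(counts - 64 * p) <= 4 * sqrt(64 * p * (1 - p))))
  expect_gt(mean(counts), 64 * p - 2 * sqrt(64 * p * (1 - p) / 6))
})

test_that("a flat logistic truth yields a coin-flip occlusion rate", {
  truth <- cohort_truth(logit = list(intercept = 0, porosity = 0, angle = 0,
                                     expansion = 0, maai = 0,
                                     brand = c(Derivo = 0, P64 = 0,
                                               Pipeline = 0, Surpass = 0)))
  tab <- generate_cohort(truth, n = 2000, seed = 11)
  rate <- mean(tab$occluded)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 2000) + 1e-9)
})

test_that("phantom measurements are noisy clipped copies of the field", {
  dep <- deploy(fd_presets("Pipeline"),
                synthetic_vessel(50, 1.7, taper = 0.1)$vessel)
  pm0 <- phantom_measurements(dep, noise_sd = 0, seed = 1)
  expect_identical(pm0$measured, pm0$predicted)
  pm <- phantom_measurements(dep, noise_sd = 0.02, seed = 2)
  expect_equal(sd(pm$measured - pm$predicted), 0.02, tolerance = 0.1)
  expect_true(all(pm$measured >= 0 & pm$measured <= 1))
  big <- phantom_measurements(dep, noise_sd = 0.8, seed = 3)
  expect_true(all(big$measured <= 1))
  expect_identical(phantom_measurements(dep, 0.02, seed = 9),
                   phantom_measurements(dep, 0.02, seed = 9))
})

test_that("good-estimate rate counts sub-threshold errors", {
  m <- runif(50, 0.5, 0.9)
  expect_equal(good_estimate_rate(m, m), 1.0)
  p <- m
  p[1:25] <- m[1:25] * 1.2      # relative error 0.2 = 2 x threshold
  expect_equal(good_estimate_rate(p, m, threshold = 0.1), 0.5)
  expect_warning(r <- good_estimate_rate(c(0.7, 0.7), c(0.7, 0)),
                 "zero measurement")
  expect_equal(r, 1.0)
  expect_equal(good_estimate_rate(c(0.7, 0.75), c(0.72, 0.70),
                                  threshold = 0.04, relative = FALSE), 0.5)
  expect_error(good_estimate_rate(1:3, 1:2), "equal length")
  expect_error(good_estimate_rate(1:3, 1:3, threshold = 0), "positive")
})

test_that("cohort truth validates its own invariants", {
  expect_error(cohort_truth(brand_mix = c(a = 0.5, b = 0.4)), "sum")
  expect_error(cohort_truth(morphology = list(
    meanlog = c(depth = 1, width = 1, volume = 1, neck_max = 1, neck_min = 1),
    sdlog = c(depth = 1, width = 1, volume = 1, neck_max = 1, neck_min = 1),
    rho = -0.5)))
  expect_error(generate_cohort(n = 5, seed = 1), "at least 10")
})
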