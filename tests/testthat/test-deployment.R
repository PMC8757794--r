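test_that("nominal deployment reproduces the nominal state exactly", {
  spec <- fd_presets("Pipeline")
  tube <- straight_tube(spec$phi_nom, length = 40)
  dep <- deploy(spec, tube)
  expect_true(all(dep$expansion == 100))
  expect_equal(unique(as.vector(dep$mesh_angle)), 2 * spec$alpha_nom)
  expect_equal(unique(as.vector(dep$porosity)), nominal_porosity(spec))
  M <- nominal_row_count(spec)
  expect_identical(nrow(dep$rows), M)
  expect_equal(deployed_length(dep),
               M * 2 * spec$S * cos(spec$alpha_nom * pi / 180))
  # within one cell row of the nominal length
  expect_lt(abs(deployed_length(dep) - spec$L_nom),
            2 * spec$S * cos(spec$alpha_nom * pi / 180))
})

test_that("under-expansion lengthens the device by the cosine ratio", {
  spec <- ref_device(alpha_nom = 50, phi = 4)          # alpha(3 mm) = 35.07
  dep <- deploy(spec, straight_tube(3, length = 60))
  nominal_len <- nominal_row_count(spec) * 2 * spec$S * cos(50 * pi / 180)
  ratio <- deployed_length(dep) / nominal_len
  expect_equal(ratio, cos(35.06696 * pi / 180) / cos(50 * pi / 180),
               tolerance = 1e-6)
  expect_equal(ratio, 1.2733, tolerance = 1e-4)
})

test_that("deployed length grows monotonically as a uniform tube narrows", {
  spec <- ref_device(alpha_nom = 60)
  lens <- vapply(c(4, 3.6, 3.2, 2.8), function(d)
    deployed_length(deploy(spec, straight_tube(d, length = 60))), numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("row count is conserved across vessels (wire-length surrogate)", {
  spec <- fd_presets("Derivo")
  vessels <- list(straight_tube(4.5, 80), straight_tube(3.4, 80),
                  synthetic_vessel(80, 1.9, taper = 0.1,
                                   bend_curvature = 0.04)$vessel)
  rows <- vapply(vessels, function(v) nrow(deploy(spec, v)$rows), integer(1))
  expect_true(all(rows == nominal_row_count(spec)))
})

test_that("straight vessels give circumferentially constant fields", {
  spec <- fd_presets("Surpass")
  dep <- deploy(spec, straight_tube(3.5, length = 60))
  spread <- apply(dep$porosity, 1, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  spread_a <- apply(dep$mesh_angle, 1, function(x) diff(range(x)))
  expect_true(all(spread_a < 1e-12))
})

test_that("bends close the mesh on the inner wall for open braids", {
  # alpha_row approx 51 deg > 45: porosity(inner) < porosity(outer) per row
  spec <- ref_device(alpha_nom = 60, phi = 4, L = 20)
  bent <- synthetic_vessel(60, 1.8, bend_curvature = 0.05, ds = 0.25)$vessel
  dep <- deploy(spec, bent)
  expect_true(all(dep$rows$alpha_row > 45))
  inner <- dep$porosity[, dep$theta == 0]
  outer <- dep$porosity[, dep$theta == 180]
  expect_true(all(inner < outer))
  # and the ordering reverses when the braid is below 45 degrees
  spec2 <- ref_device(alpha_nom = 42, phi = 4, L = 20)
  dep2 <- deploy(spec2, bent)
  expect_true(all(dep2$rows$alpha_row < 45))
  expect_true(all(dep2$porosity[, dep2$theta == 0] >
                    dep2$porosity[, dep2$theta == 180]))
})

test_that("porosity and mesh angle stay within physical bounds", {
  spec <- fd_presets("P64")
  dep <- deploy(spec, synthetic_vessel(60, 1.7, taper = 0.15,
                                       bend_curvature = 0.07)$vessel)
  expect_true(all(dep$porosity >= 0 & dep$porosity <= 1))
  expect_true(all(dep$mesh_angle > 0 & dep$mesh_angle < 180))
  expect_true(all(dep$expansion <= 100))
})

test_that("deployment errors identify the failure", {
  spec <- fd_presets("Pipeline")
  expect_error(deploy(spec, straight_tube(4, length = 10)),
               "overruns the vessel")
  expect_error(deploy(spec, straight_tube(4, length = 10)), "rows")
  narrow <- straight_tube(0.25, length = 60)   # below braid closure
  expect_error(deploy(spec, narrow), "s = ")
  expect_error(deploy(spec, straight_tube(4), n_theta = 4), "n_theta")
  expect_error(deploy(spec, straight_tube(4), distal_s = 99), "distal_s")
})

test_that("region summaries aggregate the selected rows", {
  spec <- fd_presets("Pipeline")
  tube <- straight_tube(spec$phi_nom, length = 40)
  dep <- deploy(spec, tube)
  s <- region_summary(dep, aneurysm_region(10, 18))
  expect_equal(s$porosity_sd, 0)
  expect_equal(s$angle_sd, 0)
  expect_equal(s$expansion_sd, 0)
  expect_equal(s$porosity_mean, nominal_porosity(spec))
  expect_equal(s$angle_mean, 2 * spec$alpha_nom)
  expect_equal(s$expansion_mean, 100)
  expect_error(region_summary(dep, aneurysm_region(39.5, 39.9)),
               "\\[39.50, 39.90\\)")
})

test_that("region selection picks exactly the rows whose centers fall inside", {
  # two-diameter vessel: region covering one row reproduces that row's stats
  spec <- ref_device(alpha_nom = 55)
  v <- vessel_model(seq(0, 60, 0.5),
                    cbind(seq(0, 60, 0.5), 0, 0),
                    ifelse(seq(0, 60, 0.5) < 30, 1.9, 1.6))
  dep <- deploy(spec, v)
  i <- 5
  lo <- dep$rows$s_center[i] - 1e-6; hi <- dep$rows$s_center[i] + 1e-6
  s <- region_summary(dep, aneurysm_region(lo, hi))
  expect_equal(s$porosity_mean, mean(dep$porosity[i, ]))
  expect_equal(s$n_points, length(dep$theta))
})

test_that("hand-built two-row summary gives the textbook mean and SD", {
  dev <- structure(list(
    spec = ref_device(), vessel_name = "hand", distal_s = 0,
    rows = data.frame(s_center = c(1, 2), local_diameter = 4,
                      alpha_row = 50, row_length = 0.5, kappa = 0),
    theta = 0,
    porosity = matrix(c(0.70, 0.80), ncol = 1),
    mesh_angle = matrix(c(100, 100), ncol = 1),
    expansion = matrix(c(90, 90), ncol = 1)), class = "fd_deployment")
  s <- region_summary(dev, aneurysm_region(0, 3))
  expect_equal(s$porosity_mean, 0.75)
  expect_equal(s$porosity_sd, 0.05)     # population SD
  expect_identical(s$n_points, 2L)
})

test_that("field export is deterministic and row-major", {
  spec <- fd_presets("Pipeline")
  dep <- deploy(spec, straight_tube(3.6, length = 50))
  df <- as.data.frame(dep)
  K <- length(dep$theta)
  expect_equal(df$s_mm[1:K], rep(dep$rows$s_center[1], K))
  expect_equal(df$theta_deg[1:K], dep$theta)
  expect_equal(df$porosity + df$coverage, rep(1, nrow(df)))
  expect_identical(df, as.data.frame(dep))
})
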