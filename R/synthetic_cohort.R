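# Run expr with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ground truth for the synthetic cohort generator
#'
#' Collects every parameter of the data-generating process so that
#' recovery tests can compare fitted models against a known truth. The
#' defaults emulate the study conditions of the motivating cohort:
#' brand mix Derivo/P64/Pipeline/Surpass = 8/8/26/22, follow-ups in the
#' 6--12 month range, an occlusion rate near 51/64 with a negative MAAI
#' coefficient (-0.25), a mean TTO of 6.92 months, a generating TTO
#' R^2 of 0.92, and equicorrelated (rho = 0.92) log-normal morphology so
#' the first principal component carries (1 + 3 rho)/4 = 94\% of the
#' four-variable variance. Mesh effects on occlusion are zero (the mesh
#' variables were not significant for occlusion); porosity and, weakly,
#' mesh angle drive TTO, while expansion and brand do not. The age effect
#' on TTO is non-linear: young and old patients occlude faster than
#' mid-age ones, encoded as age-group offsets on fixed breaks.
#'
#' @param logit named list of occlusion-model coefficients on centred
#'   mesh covariates: `intercept`, `porosity`, `angle`, `expansion`,
#'   `maai`, `brand` (named offsets).
#' @param tto named list for the TTO linear model: `mean_months`,
#'   `porosity` (months per porosity fraction), `angle` (months per
#'   degree), `expansion`, `maai`, `brand` offsets, `age_offsets`
#'   (young/mid/old), `age_breaks` (years), `target_r2`, and optional
#'   fixed `residual_sd` (months; when `NULL` the SD is derived from the
#'   realised linear predictor so the generating R^2 equals `target_r2`).
#' @param morphology list with `meanlog`, `sdlog` (named, 5 variables)
#'   and equicorrelation `rho` (must exceed -1/3 for a valid 4-variable
#'   correlation matrix).
#' @param brand_mix named probabilities over the four brand presets.
#' @param fu_range follow-up window, months.
#' @param expansion list `mean`, `sd`, `lo`, `hi`: truncated-normal
#'   distribution of the target expansion fraction of deployed devices.
#' @param age_range uniform age range, years.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(
    logit = list(
      # intercept calibrated so the *marginal* occlusion rate is 51/64:
      # with eta = b0 - 0.25 * MAAI and MAAI SD ~ 1.93, the logit-normal
      # correction is qlogis(51/64) * sqrt(1 + 0.346 * (0.25 * 1.93)^2)
      intercept = stats::qlogis(51 / 64) * sqrt(1 + 0.346 * 0.483^2),
      porosity = 0, angle = 0, expansion = 0, maai = -0.25,
      brand = c(Derivo = 0, P64 = 0, Pipeline = 0, Surpass = 0)),
    tto = list(mean_months = 6.92, porosity = 8, angle = -0.035,
               expansion = 0, maai = 0,
               brand = c(Derivo = 0, P64 = 0, Pipeline = 0, Surpass = 0),
               age_offsets = c(young = 0, mid = 3.6, old = 0.3),
               age_breaks = c(45, 60), target_r2 = 0.92,
               residual_sd = NULL),
    morphology = list(
      meanlog = c(depth = log(3.3), width = log(3.6), volume = log(30),
                  neck_max = log(4.0), neck_min = log(3.2)),
      sdlog = c(depth = 0.55, width = 0.5, volume = 1.0,
                neck_max = 0.45, neck_min = 0.45),
      rho = 0.92),
    brand_mix = c(Derivo = 8, P64 = 8, Pipeline = 26, Surpass = 22) / 64,
    fu_range = c(6, 12),
    expansion = list(mean = 0.87, sd = 0.05, lo = 0.62, hi = 0.98),
    age_range = c(30, 75)) {
  stopifnot(abs(sum(brand_mix) - 1) < 1e-8,
            morphology$rho > -1 / 3, morphology$rho < 1,
            fu_range[1] < fu_range[2],
            is.null(tto$residual_sd) || tto$residual_sd > 0,
            tto$target_r2 > 0, tto$target_r2 < 1)
  structure(list(logit = logit, tto = tto, morphology = morphology,
                 brand_mix = brand_mix, fu_range = fu_range,
                 expansion = expansion, age_range = age_range,
                 label = "synthetic truth"),
            class = "cohort_truth")
}

#' Build a synthetic vessel with a sidewall aneurysm neck
#'
#' Constructs a planar circular-arc (or straight) centerline with linearly
#' tapering radius, a declared neck interval and a morphology record
#' sampled consistently with the neck width. The measured curvature of the
#' generated centerline equals `bend_curvature` away from the endpoints.
#'
#' @param length centerline length, mm.
#' @param base_radius lumen radius at the distal end, mm.
#' @param taper total fractional radius loss over the length (0 = tube).
#' @param bend_curvature centerline curvature, 1/mm
#'   (`bend_curvature * base_radius < 1`).
#' @param seed optional integer seed for the morphology sampling; without
#'   a seed the morphology is deterministic (mid-distribution values).
#' @param ds sample spacing, mm.
#' @param neck_center,neck_width position and longitudinal extent of the
#'   aneurysm neck, mm.
#' @return A list with elements `vessel` ([vessel_model()]), `region`
#'   ([aneurysm_region()]) and `morphology` ([aneurysm_morphology()]).
#' @export
synthetic_vessel <- function(length, base_radius, taper = 0,
                             bend_curvature = 0, seed = NULL, ds = 0.5,
                             neck_center = length / 2, neck_width = 4) {
  if (length <= 0 || base_radius <= 0 || taper < 0 || taper >= 1 ||
      bend_curvature < 0)
    stop("infeasible vessel geometry", call. = FALSE)
  if (bend_curvature * base_radius >= 1)
    stop("infeasible geometry: bend_curvature * base_radius must be < 1",
         call. = FALSE)
  n <- max(4L, ceiling(length / ds) + 1L)
  s <- seq(0, length, length.out = n)
  if (bend_curvature > 1e-12) {
    R <- 1 / bend_curvature
    phi <- s / R
    xyz <- cbind(R * sin(phi), R * (1 - cos(phi)), 0)
  } else {
    xyz <- cbind(s, 0, 0)
  }
  radius <- base_radius * (1 - taper * s / length)
  vessel <- vessel_model(s, xyz, radius, name = "synthetic")
  region <- aneurysm_region(max(0, neck_center - neck_width / 2),
                            min(length, neck_center + neck_width / 2))
  morph <- .with_seed(seed, {
    u <- if (is.null(seed)) c(0.85, 1.0, 1.1) else stats::runif(3, 0.7, 1.3)
    neck_max <- neck_width
    neck_min <- min(neck_max, 0.8 * neck_max * u[1])
    depth <- neck_max * u[2]
    width <- depth * u[3]
    aneurysm_morphology(depth = depth, width = width,
                        volume = pi / 6 * depth * width * neck_max,
                        neck_max = neck_max, neck_min = neck_min)
  })
  list(vessel = vessel, region = region, morphology = morph)
}

# truncated-normal draw by rejection (vectorised)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.age_group <- function(age, breaks) {
  cut(age, c(-Inf, breaks, Inf), labels = c("young", "mid", "old"))
}

#' Generate a synthetic aneurysm cohort with known ground truth
#'
#' Runs the full forward pipeline for each case: draws a brand, age and
#' equicorrelated log-normal morphology; builds a synthetic vessel sized
#' for the brand's device at a target expansion; virtually deploys the
#' preset device ([deploy()]); summarises porosity, mesh angle and
#' expansion over the neck region; then draws the occlusion outcome from a
#' logistic model and, for occluded cases, the TTO from a linear model
#' truncated to (0, 12\] with the follow-up time at or after the observed
#' occlusion. Deployment failures (device overrunning a too-short vessel)
#' are retried with resampled geometry up to 20 times.
#'
#' Mesh covariates enter both generating models centred at their realised
#' means, so the truth intercepts are interpretable as the occlusion
#' log-odds and mean TTO of the cohort. The attached `truth` attribute
#' records the uncentred coefficient vectors in the same parameterisation
#' as the fitted models, the realised residual SD, and the latent linear
#' predictors, for use in recovery tests.
#'
#' @param truth a [cohort_truth()].
#' @param n number of aneurysms (>= 10).
#' @param seed integer seed; the same `(truth, n, seed)` reproduces the
#'   cohort exactly.
#' @param n_theta,ds deployment discretisation (see [deploy()]).
#' @return A data.frame with one row per aneurysm (`patient_id`, `age`,
#'   `sex`, `brand_label`, morphology columns, `maai`, mesh summary
#'   columns, `occluded`, `tto_months`, `fu_months`) and attributes
#'   `truth` (generator metadata) and `maai_fit`.
#' @export
generate_cohort <- function(truth = cohort_truth(), n = 64, seed = 1,
                            n_theta = 16L, ds = 0.5) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  presets <- fd_presets()
  mo <- truth$morphology
  vars5 <- names(mo$meanlog)
  .with_seed(seed, {
    brand <- sample(names(truth$brand_mix), n, replace = TRUE,
                    prob = truth$brand_mix)
    age <- stats::runif(n, truth$age_range[1], truth$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.72, 0.28))
    # equicorrelated morphology via a one-factor model on the log scale
    f <- stats::rnorm(n)
    z <- sqrt(mo$rho) * f +
      sqrt(1 - mo$rho) * matrix(stats::rnorm(n * length(vars5)), n)
    M <- exp(sweep(sweep(z, 2, mo$sdlog[vars5], "*"), 2, mo$meanlog[vars5],
                   "+"))
    colnames(M) <- vars5
    # enforce neck_min <= neck_max without disturbing the marginals much
    swap <- M[, "neck_min"] > M[, "neck_max"]
    tmp <- M[swap, "neck_min"]
    M[swap, "neck_min"] <- M[swap, "neck_max"]; M[swap, "neck_max"] <- tmp

    sm <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("porosity_mean", "porosity_sd",
                                         "angle_mean", "angle_sd",
                                         "expansion_mean", "expansion_sd")))
    for (i in seq_len(n)) {
      spec <- presets[[brand[i]]]
      done <- FALSE
      for (try in 1:20) {
        e <- .rtruncnorm(1, truth$expansion$mean, truth$expansion$sd,
                         truth$expansion$lo, truth$expansion$hi)
        taper <- stats::runif(1, 0, 0.08)
        bend <- stats::runif(1, 0, 0.08)
        len <- 2.4 * spec$L_nom + 12
        sv <- synthetic_vessel(len, e * spec$phi_nom / 2, taper = taper,
                               bend_curvature = bend, ds = ds)
        dep <- tryCatch(deploy(spec, sv$vessel, distal_s = 2,
                               n_theta = n_theta),
                        error = function(e) NULL)
        if (is.null(dep)) next
        w <- min(max(M[i, "neck_max"], 1.5), 8)
        center <- 2 + 0.5 * deployed_length(dep)
        reg <- aneurysm_region(center - w / 2, center + w / 2)
        s <- tryCatch(region_summary(dep, reg), error = function(e) NULL)
        if (is.null(s)) next
        sm[i, ] <- c(s$porosity_mean, s$porosity_sd, s$angle_mean,
                     s$angle_sd, s$expansion_mean, s$expansion_sd)
        done <- TRUE
        break
      }
      if (!done)
        stop("deployment failed repeatedly for case ", i, " (brand ",
             brand[i], ")", call. = FALSE)
    }

    tab <- data.frame(patient_id = seq_len(n), age = age, sex = sex,
                      brand_label = brand, as.data.frame(M), sm)
    mfit <- fit_maai(tab)
    tab$maai <- mfit$scores

    # occlusion: logistic model on centred mesh covariates
    lg <- truth$logit
    ctr <- c(porosity = mean(tab$porosity_mean),
             angle = mean(tab$angle_mean),
             expansion = mean(tab$expansion_mean))
    eta_occ <- lg$intercept +
      lg$porosity * (tab$porosity_mean - ctr["porosity"]) +
      lg$angle * (tab$angle_mean - ctr["angle"]) +
      lg$expansion * (tab$expansion_mean - ctr["expansion"]) +
      lg$maai * tab$maai + lg$brand[brand]
    eta_occ <- unname(eta_occ)
    tab$occluded <- stats::rbinom(n, 1, stats::plogis(eta_occ))

    # TTO: linear model with mean anchored on the occluded subset
    tt <- truth$tto
    occ <- tab$occluded == 1
    tab$tto_months <- NA_real_
    tab$fu_months <- NA_real_
    eta_tto <- rep(NA_real_, n)
    sigma <- tt$residual_sd
    base <- NA_real_
    if (sum(occ) >= 2) {
      ag <- .age_group(tab$age, tt$age_breaks)
      contrib <- tt$age_offsets[as.character(ag)] + tt$brand[brand] +
        tt$porosity * tab$porosity_mean + tt$angle * tab$angle_mean +
        tt$expansion * tab$expansion_mean + tt$maai * tab$maai
      contrib <- unname(contrib)
      base <- tt$mean_months - mean(contrib[occ])
      eta <- base + contrib
      if (is.null(sigma)) {
        s_eta <- stats::sd(eta[occ])
        sigma <- if (s_eta > 0)
          s_eta * sqrt((1 - tt$target_r2) / tt$target_r2) else 0.5
      }
      tto <- eta[occ] + stats::rnorm(sum(occ), 0, sigma)
      for (k in 1:1000) {
        bad <- tto <= 0 | tto > 12
        if (!any(bad)) break
        tto[bad] <- eta[occ][bad] + stats::rnorm(sum(bad), 0, sigma)
      }
      tto <- pmin(pmax(tto, 0.1), 12)
      tab$tto_months[occ] <- tto
      # follow-up is the angiogram at which occlusion is observed: at or
      # after the occlusion, inside the 6-12 month window
      tab$fu_months[occ] <- stats::runif(sum(occ), pmax(6, tto), 12)
      eta_tto <- eta
      eta_tto[!occ] <- NA_real_
    }
    tab$fu_months[!occ] <- stats::runif(sum(!occ), truth$fu_range[1],
                                        truth$fu_range[2])

    brands <- sort(names(truth$brand_mix))
    ref <- brands[1]
    logit_unc <- c(
      "(Intercept)" = unname(lg$intercept -
        lg$porosity * ctr[["porosity"]] - lg$angle * ctr[["angle"]] -
        lg$expansion * ctr[["expansion"]] + lg$brand[[ref]]),
      porosity_mean = lg$porosity, angle_mean = lg$angle,
      expansion_mean = lg$expansion, maai = lg$maai,
      stats::setNames(lg$brand[brands[-1]] - lg$brand[[ref]],
                      paste0("brand_label", brands[-1])))
    tto_unc <- c(
      "(Intercept)" = unname(base + tt$brand[[ref]]),
      stats::setNames(tt$brand[brands[-1]] - tt$brand[[ref]],
                      paste0("brand_label", brands[-1])),
      age_groupmid = unname(tt$age_offsets[["mid"]] -
                              tt$age_offsets[["young"]]),
      age_groupold = unname(tt$age_offsets[["old"]] -
                              tt$age_offsets[["young"]]),
      porosity_mean = tt$porosity, angle_mean = tt$angle,
      expansion_mean = tt$expansion, maai = tt$maai)

    attr(tab, "truth") <- list(
      truth = truth, seed = seed, n = n,
      logit_coef = logit_unc, tto_coef = tto_unc,
      tto_sigma = sigma, age_breaks = tt$age_breaks,
      eta_logit = eta_occ, eta_tto = eta_tto,
      label = truth$label)
    attr(tab, "maai_fit") <- mfit
    tab
  })
}

#' Emulated phantom porosity measurements
#'
#' Emulates measuring the porosity of a deployed device on a silicon
#' phantom: the simulated per-sample porosity field plus i.i.d. Gaussian
#' measurement noise, clipped to \[0, 1\].
#'
#' @param dev an [deploy()] result.
#' @param noise_sd measurement noise SD, porosity fraction.
#' @param seed optional integer seed.
#' @return A data.frame with `predicted` (the simulated field, in the
#'   deterministic export order of [as.data.frame.fd_deployment()]) and
#'   `measured`.
#' @export
phantom_measurements <- function(dev, noise_sd, seed = NULL) {
  stopifnot(inherits(dev, "fd_deployment"), noise_sd >= 0)
  p <- as.data.frame(dev)$porosity
  m <- .with_seed(seed, p + stats::rnorm(length(p), 0, noise_sd))
  data.frame(predicted = p, measured = pmin(pmax(m, 0), 1))
}

#' Fraction of good porosity estimates
#'
#' Fraction of paired (prediction, measurement) samples whose error is
#' below a threshold -- by default the relative error
#' `|predicted - measured| / measured < threshold`. Pairs with a zero
#' measurement are excluded with a warning. Used to contrast the
#' spatially resolved porosity prediction with the constant
#' manufacturer-tag baseline ([nominal_porosity()]).
#'
#' @param predicted,measured equal-length numeric vectors.
#' @param threshold error threshold (default 0.10).
#' @param relative if `FALSE`, use absolute error in porosity points.
#' @return Fraction in \[0, 1\].
#' @export
good_estimate_rate <- function(predicted, measured, threshold = 0.1,
                               relative = TRUE) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (relative && any(measured == 0)) {
    warning(sum(measured == 0),
            " pair(s) with zero measurement excluded from the rate")
    keep <- measured != 0
    predicted <- predicted[keep]; measured <- measured[keep]
  }
  err <- if (relative) abs(predicted - measured) / abs(measured)
         else abs(predicted - measured)
  mean(err < threshold)
}
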