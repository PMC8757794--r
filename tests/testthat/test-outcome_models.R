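test_that("logit IRLS matches a brute-force likelihood maximiser", {
  set.seed(71)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.4 + 0.8 * x))
  tab <- data.frame(occluded = y, maai = x,
                    porosity_mean = runif(200, 0.6, 0.8))
  fit <- fit_occlusion_logit(tab, terms = "maai")
  mle <- grid_logit_mle(y, x, b0_range = c(-2, 2), b1_range = c(-2, 3))
  expect_equal(unname(coef(fit)), mle, tolerance = 1e-3)
})

test_that("occlusion logit recovers the generating MAAI slope", {
  # generating slope -0.25 at n = 5000: estimate within +/- 0.05
  tab <- generate_cohort(n = 5000, seed = 17)
  fit <- fit_occlusion_logit(tab)
  expect_lt(abs(unname(coef(fit)["maai"]) - (-0.25)), 0.05)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_true(all(fit$coefficients[, "p_value"] >= 0 &
                    fit$coefficients[, "p_value"] <= 1))
  expect_identical(fit$n, 5000L)
})

test_that("logit degenerate inputs error rather than returning NaN", {
  tab <- generate_cohort(n = 30, seed = 3)
  tab$flat <- 0
  expect_error(fit_occlusion_logit(tab, terms = c("maai", "flat")),
               "zero variance")
  tab1 <- tab; tab1$occluded <- 1
  expect_error(fit_occlusion_logit(tab1), "single class")
  expect_error(fit_occlusion_logit(tab[1:5, ]), "at least 10")
})

test_that("separation is flagged, not silently mis-reported", {
  set.seed(81)
  x <- c(rnorm(25, -3), rnorm(25, 3))
  tab <- data.frame(occluded = rep(c(0, 1), each = 25), maai = x)
  fit <- fit_occlusion_logit(tab, terms = "maai")
  expect_true(fit$separation)
})

test_that("ANCOVA decomposition is order-dependent but the fit is not", {
  tab <- generate_cohort(n = 200, seed = 23)
  o1 <- c("porosity_mean", "angle_mean", "expansion_mean", "maai")
  o2 <- rev(o1)
  f1 <- fit_tto_ancova(tab, covariate_order = o1)
  f2 <- fit_tto_ancova(tab, covariate_order = o2)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  ss1 <- f1$sequential[["Sum Sq"]]; ss2 <- f2$sequential[["Sum Sq"]]
  expect_false(isTRUE(all.equal(
    ss1[rownames(f1$sequential) != "Residuals"],
    ss2[rownames(f2$sequential) != "Residuals"])))
  expect_equal(sum(ss1), sum(ss2), tolerance = 1e-8)
  # sequential SS are non-negative and decompose the total SS
  expect_true(all(ss1 >= 0))
  y <- f1$data$tto_months
  expect_equal(sum(ss1), sum((y - mean(y))^2), tolerance = 1e-8)
  expect_true(f1$r_squared >= 0 && f1$r_squared <= 1)
})

test_that("ANCOVA subsets to occluded cases within 12 months", {
  tab <- generate_cohort(n = 150, seed = 29)
  f <- fit_tto_ancova(tab)
  expect_identical(f$n, sum(tab$occluded == 1 & tab$tto_months <= 12,
                            na.rm = TRUE))
  tab0 <- tab; tab0$occluded <- 0
  expect_error(fit_tto_ancova(tab0), "empty")
  # a brand level with a single occluded row is named in the error
  tab1 <- tab[tab$occluded == 1, ]
  tab1$brand_label[1] <- "Rare"
  expect_error(fit_tto_ancova(tab1), "Rare")
})

test_that("age handling options change the age term only", {
  tab <- generate_cohort(n = 200, seed = 31)
  f_t <- fit_tto_ancova(tab, age_handling = "tertile")
  f_l <- fit_tto_ancova(tab, age_handling = "linear")
  f_q <- fit_tto_ancova(tab, age_handling = "quadratic")
  f_b <- fit_tto_ancova(tab, age_handling = "breaks", age_breaks = c(47, 53))
  expect_true("age_groupmid" %in% names(coef(f_t)))
  expect_true("age" %in% names(coef(f_l)))
  expect_true(any(grepl("poly", names(coef(f_q)))))
  expect_equal(f_b$age_handling$breaks, c(47, 53))
  expect_error(fit_tto_ancova(tab, age_handling = "breaks"), "age_breaks")
})

test_that("residual diagnostics report Shapiro-Wilk and Levene", {
  tab <- generate_cohort(n = 200, seed = 37)
  f <- fit_tto_ancova(tab)
  d <- residual_diagnostics(f)
  expect_true(d$normality$p_value >= 0 && d$normality$p_value <= 1)
  expect_true(d$homogeneity$p_value >= 0 && d$homogeneity$p_value <= 1)

  # identical residuals across groups: zero homogeneity statistic
  res <- rep(c(-2, -1, 0, 1, 2), 3)
  g <- rep(c("a", "b", "c"), each = 5)
  d0 <- residual_diagnostics(res, g)
  expect_equal(d0$homogeneity$statistic, 0)

  # singleton groups are excluded and reported
  d1 <- residual_diagnostics(c(rnorm(20), 5), c(rep(c("a", "b"), 10), "solo"))
  expect_identical(d1$excluded_groups, "solo")
  expect_error(residual_diagnostics(rnorm(5), rep("a", 5)), "at least 8")
})

test_that("an inflated-variance group is detected with high power", {
  set.seed(91)
  hits <- 0; nrep <- 200
  for (r in 1:nrep) {
    res <- c(rnorm(50), rnorm(50), rnorm(50, sd = 3))
    g <- rep(c("a", "b", "c"), each = 50)
    d <- residual_diagnostics(res, g)
    hits <- hits + (d$homogeneity$p_value < 0.01)
  }
  expect_gte(hits / nrep, 0.90)
})

test_that("TTO summary is plain mean and standard error", {
  tab <- data.frame(occluded = c(1, 1, 0), tto_months = c(6, 8, NA),
                    fu_months = c(8, 9, 10))
  s <- tto_summary(tab)
  expect_equal(s$mean, 7)
  expect_equal(s$se, 1)
  expect_identical(s$n, 2L)
  tab2 <- data.frame(occluded = rep(1, 5), tto_months = rep(7.5, 5),
                     fu_months = rep(9, 5))
  expect_equal(tto_summary(tab2)$se, 0)
  expect_error(tto_summary(tab[1, ]), "at least 2")
})
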