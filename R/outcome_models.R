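#' Default mesh / morphology covariate names of the cohort schema
#' @keywords internal
.default_logit_terms <- c("porosity_mean", "angle_mean", "expansion_mean",
                          "maai", "brand_label")

.check_cohort_cols <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

.zero_variance <- function(table, terms) {
  num <- terms[vapply(table[terms], is.numeric, logical(1))]
  bad <- num[vapply(table[num], function(x) stats::sd(x) == 0, logical(1))]
  if (length(bad))
    stop("covariate(s) with zero variance: ", paste(bad, collapse = ", "),
         call. = FALSE)
}

.as_brand_factor <- function(x, ref_level = NULL) {
  f <- factor(x)
  if (!is.null(ref_level)) {
    if (!ref_level %in% levels(f))
      stop("reference level '", ref_level, "' not present", call. = FALSE)
    f <- stats::relevel(f, ref_level)
  }
  f
}

#' Occlusion logistic regression
#'
#' Models the binary 12-month occlusion outcome on the mesh morphology of
#' the deployed device (porosity, mesh angle, expansion means over the
#' aneurysm region), the MAAI morphology index and the FD brand
#' (dummy-coded against a reference level, by default the alphabetically
#' first brand). Fitting is maximum likelihood via iteratively reweighted
#' least squares ([stats::glm()]); Wald z tests are reported per
#' coefficient and (quasi-)separation is detected and flagged rather than
#' failing silently.
#'
#' @param table a cohort data.frame (see [generate_cohort()] for the
#'   schema) with an `occluded` column in \{0, 1\}.
#' @param terms model terms; numeric columns enter linearly,
#'   `brand_label` as a factor.
#' @param ref_level reference brand level for dummy coding (default:
#'   first level alphabetically).
#' @return An object of class `occlusion_logit`: `coefficients` table
#'   (estimate, std. error, Wald z, p), `log_likelihood`, `n`,
#'   `converged`, `separation`, and the underlying `glm` fit.
#' @export
fit_occlusion_logit <- function(table, terms = .default_logit_terms,
                                ref_level = NULL) {
  .check_cohort_cols(table, c("occluded", terms))
  if (nrow(table) < 10L)
    stop("need at least 10 rows to fit the occlusion model", call. = FALSE)
  if (!all(table$occluded %in% c(0, 1)))
    stop("'occluded' must be coded 0/1", call. = FALSE)
  if (length(unique(table$occluded)) < 2L)
    stop("both occluded and patent aneurysms are required; the outcome has ",
         "a single class", call. = FALSE)
  .zero_variance(table, terms)
  dat <- table[, c("occluded", terms)]
  if ("brand_label" %in% terms)
    dat$brand_label <- .as_brand_factor(dat$brand_label, ref_level)
  form <- stats::reformulate(terms, response = "occluded")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  separation <- sep_warn || any(mu < 1e-8 | mu > 1 - 1e-8)
  cf <- stats::coef(summary(fit))
  colnames(cf) <- c("estimate", "std_error", "z", "p_value")
  structure(list(coefficients = cf,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = nrow(dat), converged = fit$converged,
                 separation = separation, terms = terms, glm = fit),
            class = "occlusion_logit")
}

#' @export
coef.occlusion_logit <- function(object, ...) object$coefficients[, "estimate"]

#' @export
predict.occlusion_logit <- function(object, newdata = NULL,
                                    type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) stats::predict(object$glm, type = type)
  else stats::predict(object$glm, newdata = newdata, type = type)
}

#' Wald confidence intervals for an occlusion logit fit
#' @param object an [fit_occlusion_logit()] result.
#' @param parm optional coefficient names.
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.occlusion_logit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf[, "estimate"] - z * cf[, "std_error"],
              cf[, "estimate"] + z * cf[, "std_error"])
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.occlusion_logit <- function(x, ...) {
  cat("Occlusion logistic model (n =", x$n, ", log-likelihood",
      sprintf("%.2f", x$log_likelihood), ")\n")
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: (quasi-)separation detected\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.occlusion_logit <- function(object, ...) print(object)

#' Time-to-occlusion ANCOVA with sequential covariate correction
#'
#' Linear model for the time-to-occlusion (months) of occluded aneurysms:
#' FD brand and an age term enter as factors, then the continuous mesh and
#' morphology covariates are entered \emph{in the order given}, and the
#' sequential (entry-order, Type I) sum-of-squares decomposition is
#' reported with F tests. Because sequential sums of squares depend on
#' entry order, refitting with a different `covariate_order` changes the
#' decomposition table but not the fitted values, residuals or R^2.
#' Marginal (drop-one) F tests are reported alongside. No multiple-testing
#' correction is applied.
#'
#' Only rows with `occluded == 1` and `tto_months <= max_tto` are used
#' (occlusion observed within the study's 12-month framing).
#'
#' Age handling: a per-year factor is unidentifiable in small cohorts and
#' the age pattern is non-linear (young and old occlude faster than
#' mid-age), so the default bins age into tertiles; alternatives are
#' explicit `age_breaks`, a linear term, or an orthogonal quadratic.
#'
#' @param table cohort data.frame (schema of [generate_cohort()]).
#' @param covariate_order character vector of continuous covariates in
#'   entry order.
#' @param age_handling one of "tertile", "breaks", "linear", "quadratic".
#' @param age_breaks interior cut points (years) when
#'   `age_handling = "breaks"`.
#' @param ref_level reference brand level for dummy coding.
#' @param max_tto upper TTO bound for inclusion, months.
#' @return An object of class `tto_ancova`: the `lm` fit, `sequential`
#'   ANOVA table, `marginal` (drop-one) table, `r_squared`, `entry_order`,
#'   `n`, the model data, and `age_handling` metadata.
#' @export
fit_tto_ancova <- function(table,
                           covariate_order = c("porosity_mean", "angle_mean",
                                               "expansion_mean", "maai"),
                           age_handling = c("tertile", "breaks", "linear",
                                            "quadratic"),
                           age_breaks = NULL, ref_level = NULL,
                           max_tto = 12) {
  age_handling <- match.arg(age_handling)
  .check_cohort_cols(table, c("occluded", "tto_months", "age", "brand_label",
                              covariate_order))
  dat <- table[table$occluded == 1 & !is.na(table$tto_months) &
                 table$tto_months <= max_tto, , drop = FALSE]
  if (nrow(dat) == 0L)
    stop("no occluded aneurysms with TTO <= ", max_tto,
         " months; ANCOVA subset is empty", call. = FALSE)
  .zero_variance(dat, covariate_order)
  dat$brand_label <- .as_brand_factor(dat$brand_label, ref_level)
  age_meta <- list(mode = age_handling)
  if (age_handling == "tertile") {
    br <- stats::quantile(dat$age, c(1, 2) / 3)
    dat$age_group <- cut(dat$age, c(-Inf, br, Inf),
                         labels = c("young", "mid", "old"))
    age_meta$breaks <- unname(br)
    age_term <- "age_group"
  } else if (age_handling == "breaks") {
    if (is.null(age_breaks)) stop("age_breaks required", call. = FALSE)
    labs <- if (length(age_breaks) == 2L) c("young", "mid", "old") else NULL
    dat$age_group <- cut(dat$age, c(-Inf, age_breaks, Inf), labels = labs)
    age_meta$breaks <- age_breaks
    age_term <- "age_group"
  } else if (age_handling == "linear") {
    age_term <- "age"
  } else {
    age_term <- "poly(age, 2)"
  }
  for (fac in c("brand_label", if (grepl("age_group", age_term)) "age_group")) {
    tab <- table(dat[[fac]])
    if (any(tab < 2L))
      stop("factor '", fac, "' has level(s) with fewer than 2 rows: ",
           paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  form <- stats::reformulate(c("brand_label", age_term, covariate_order),
                             response = "tto_months")
  fit <- stats::lm(form, data = dat)
  seq_tab <- stats::anova(fit)
  marg_tab <- stats::drop1(fit, test = "F")
  sm <- summary(fit)
  structure(list(lm = fit, sequential = seq_tab, marginal = marg_tab,
                 r_squared = sm$r.squared, entry_order = covariate_order,
                 n = nrow(dat), data = dat, age_handling = age_meta,
                 multiplicity_correction = "none"),
            class = "tto_ancova")
}

#' @export
coef.tto_ancova <- function(object, ...) stats::coef(object$lm)

#' @export
residuals.tto_ancova <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.tto_ancova <- function(object, ...) stats::fitted(object$lm)

#' @export
predict.tto_ancova <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$lm)
  else stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
confint.tto_ancova <- function(object, parm, level = 0.95, ...) {
  stats::confint(object$lm, parm = parm, level = level)
}

#' @export
print.tto_ancova <- function(x, ...) {
  cat("Time-to-occlusion ANCOVA (n =", x$n, ", R^2 =",
      sprintf("%.4f", x$r_squared), ")\n")
  cat("  covariate entry order:", paste(x$entry_order, collapse = " -> "),
      "\n  age handling:", x$age_handling$mode,
      "\n  multiple-testing correction: none\n\n")
  cat("Sequential (entry-order) decomposition:\n")
  print(x$sequential)
  invisible(x)
}

#' @export
summary.tto_ancova <- function(object, ...) {
  print(object)
  cat("\nMarginal (drop-one) tests:\n")
  print(object$marginal)
  cat("\nCoefficients:\n")
  stats::printCoefmat(stats::coef(summary(object$lm)))
  invisible(object)
}

#' Residual diagnostic plot for a TTO ANCOVA
#' @param x a [fit_tto_ancova()] result.
#' @param ... passed to [plot.lm()].
#' @export
plot.tto_ancova <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$lm, which = 1:2, ...)
  invisible(x)
}

#' Residual normality and variance-homogeneity diagnostics
#'
#' Checks the ANCOVA error assumptions: a Shapiro--Wilk test of residual
#' normality and a median-centred Levene (Brown--Forsythe) test of
#' variance homogeneity across the groups of a factor. Groups with fewer
#' than 2 residuals are excluded and reported in the output.
#'
#' @param fit a [fit_tto_ancova()] result, or a numeric residual vector.
#' @param group factor name in the fit's model data (default
#'   `"brand_label"`), or, when `fit` is a numeric vector, a factor of the
#'   same length.
#' @return An object of class `fd_diagnostics`: `normality` and
#'   `homogeneity`, each `(statistic, p_value)`, plus `excluded_groups`.
#' @export
residual_diagnostics <- function(fit, group = "brand_label") {
  if (inherits(fit, "tto_ancova")) {
    res <- stats::residuals(fit$lm)
    g <- factor(fit$data[[group]])
  } else {
    res <- as.numeric(fit)
    g <- factor(group)
    if (length(g) != length(res))
      stop("group must match the residuals in length", call. = FALSE)
  }
  if (length(res) < 8L)
    stop("need at least 8 residuals for diagnostics", call. = FALSE)
  tab <- table(g)
  excluded <- names(tab)[tab < 2L]
  keep <- !(as.character(g) %in% excluded)
  sw <- stats::shapiro.test(res)
  lev <- car::leveneTest(res[keep] ~ droplevels(g[keep]), center = stats::median)
  structure(list(
    normality = list(statistic = unname(sw$statistic),
                     p_value = sw$p.value, test = "Shapiro-Wilk"),
    homogeneity = list(statistic = lev[1, "F value"],
                       p_value = lev[1, "Pr(>F)"],
                       test = "Levene (median-centred)"),
    excluded_groups = excluded
  ), class = "fd_diagnostics")
}

#' @export
print.fd_diagnostics <- function(x, ...) {
  cat(sprintf("Residual diagnostics:\n  %s: W = %.4f, p = %.4g\n",
              x$normality$test, x$normality$statistic, x$normality$p_value))
  cat(sprintf("  %s: F = %.4f, p = %.4g\n", x$homogeneity$test,
              x$homogeneity$statistic, x$homogeneity$p_value))
  if (length(x$excluded_groups))
    cat("  excluded group(s) with < 2 residuals:",
        paste(x$excluded_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Time-to-occlusion summary of a cohort
#'
#' Arithmetic mean of the observed TTO over occluded aneurysms, with its
#' standard error (sample SD / sqrt(n)).
#'
#' @param table cohort data.frame with `occluded` and `tto_months`.
#' @return A list `(mean, se, n)` in months.
#' @export
tto_summary <- function(table) {
  .check_cohort_cols(table, c("occluded", "tto_months"))
  tto <- table$tto_months[table$occluded == 1 & !is.na(table$tto_months)]
  if (length(tto) < 2L)
    stop("need at least 2 occluded aneurysms with a TTO", call. = FALSE)
  list(mean = mean(tto), se = stats::sd(tto) / sqrt(length(tto)),
       n = length(tto))
}
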