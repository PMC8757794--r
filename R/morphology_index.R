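#' Fit the MAAI aneurysm morphology index
#'
#' Reduces a set of correlated aneurysm size descriptors to a single
#' composite score -- the morphological aneurysm index (MAAI) -- by
#' principal component analysis of the correlation matrix. Variables are
#' standardised to zero mean and unit SD; the first eigenvector of the
#' correlation matrix gives the loadings and its eigenvalue share the
#' explained variance fraction. The loading sign is anchored so the
#' coefficient on the maximum neck diameter (or, if absent, the first
#' variable) is non-negative: larger aneurysms get larger MAAI scores,
#' which makes a negative occlusion-model coefficient read as "smaller
#' aneurysms are more likely to occlude".
#'
#' The default descriptor set is maximum neck diameter, depth, minimum
#' neck diameter and width; the five-variable set adding volume can be
#' requested via `variables`.
#'
#' @param records a data.frame (or list of [aneurysm_morphology()]) with
#'   the morphology variables as columns.
#' @param variables character vector of variable names to use.
#' @return An object of class `maai_fit` with elements `variable_names`,
#'   `means`, `sds`, `loadings` (unit norm), `explained_fraction`,
#'   `eigenvalues`, `n` and `scores` (of the fitting sample).
#' @seealso [predict.maai_fit()] to score new records.
#' @export
fit_maai <- function(records,
                     variables = c("neck_max", "depth", "neck_min", "width")) {
  if (!is.data.frame(records)) {
    records <- as.data.frame(do.call(rbind, lapply(records, function(r)
      unlist(unclass(r)))))
  }
  miss <- setdiff(variables, names(records))
  if (length(miss))
    stop("morphology variable(s) missing from records: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(records[, variables, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 records to fit MAAI", call. = FALSE)
  if (anyNA(X)) stop("missing values in morphology variables", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance morphology variable: ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  warn <- NULL
  if (nrow(X) < length(variables))
    warn <- "fewer records than variables; correlation matrix is singular"
  means <- colMeans(X)
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  load1 <- eig$vectors[, 1]
  anchor <- if ("neck_max" %in% variables) match("neck_max", variables) else 1L
  if (load1[anchor] < 0) load1 <- -load1
  Z <- sweep(sweep(X, 2, means), 2, sds, "/")
  fit <- structure(list(
    variable_names = variables, means = means, sds = sds,
    loadings = stats::setNames(load1, variables),
    explained_fraction = eig$values[1] / sum(eig$values),
    eigenvalues = eig$values, n = nrow(X),
    scores = as.vector(Z %*% load1),
    warning = warn
  ), class = "maai_fit")
  fit
}

#' Score records with a fitted MAAI model
#'
#' Dot product of the first-component loadings with the record
#' standardised by the fitting sample's means and SDs. A record at the
#' fitting means scores 0; scores of the fitting sample have variance
#' equal to the first eigenvalue.
#'
#' @param object a [fit_maai()] model.
#' @param newdata a data.frame (or single [aneurysm_morphology()]) holding
#'   all model variables.
#' @param ... unused.
#' @return Numeric vector of MAAI scores.
#' @export
predict.maai_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "aneurysm_morphology"))
    newdata <- as.data.frame(unclass(newdata))
  miss <- setdiff(object$variable_names, names(newdata))
  if (length(miss))
    stop("record is missing MAAI variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, object$variable_names, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$means), 2, object$sds, "/")
  as.vector(Z %*% object$loadings)
}

#' @export
coef.maai_fit <- function(object, ...) object$loadings

#' @export
print.maai_fit <- function(x, ...) {
  cat("MAAI morphology index (first principal component of",
      length(x$variable_names), "descriptors)\n")
  cat(sprintf("  n = %d, explained variance = %.1f%%\n", x$n,
              100 * x$explained_fraction))
  cat("  loadings:\n")
  print(round(x$loadings, 4))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' @export
summary.maai_fit <- function(object, ...) {
  print(object)
  cat("  eigenvalue spectrum:", paste(signif(object$eigenvalues, 4),
                                      collapse = ", "), "\n")
  invisible(object)
}

#' Serialize / restore a MAAI model as JSON
#'
#' Stores the variable names, standardisation constants, loadings and
#' explained fraction so an index fitted on one cohort can score another.
#'
#' @param object a [fit_maai()] model.
#' @param path file path.
#' @return `read_maai_json()` returns a `maai_fit` (without fitting-sample
#'   scores); `write_maai_json()` returns `path` invisibly.
#' @export
write_maai_json <- function(object, path) {
  stopifnot(inherits(object, "maai_fit"))
  jsonlite::write_json(list(
    variable_names = object$variable_names,
    means = unname(object$means), sds = unname(object$sds),
    loadings = unname(object$loadings),
    explained_fraction = object$explained_fraction, n = object$n
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maai_json
#' @export
read_maai_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    variable_names = x$variable_names,
    means = stats::setNames(x$means, x$variable_names),
    sds = stats::setNames(x$sds, x$variable_names),
    loadings = stats::setNames(x$loadings, x$variable_names),
    explained_fraction = x$explained_fraction,
    eigenvalues = NULL, n = x$n, scores = NULL, warning = NULL
  ), class = "maai_fit")
}
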