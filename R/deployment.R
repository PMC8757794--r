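#' Virtually deploy a braided device along a vessel
#'
#' Marches the device row by row from its distal anchor toward the proximal
#' end, reproducing the two mechanisms that shape the local mesh of a
#' braided FD:
#' \itemize{
#'   \item \emph{Foreshortening}: each cell row spans
#'     \eqn{2 S \cos\alpha} longitudinally, with the local half-angle
#'     \eqn{\alpha} set by the local vessel diameter through
#'     [halfangle_at_diameter()]. Rows are conserved (wire length
#'     surrogate), so under-expanded devices lengthen.
#'   \item \emph{Curvature modulation}: on a bent vessel the inner wall is
#'     longitudinally compressed and the outer wall stretched. Each
#'     circumferential sample at angle \eqn{\theta} (measured from the
#'     curvature normal, i.e. \eqn{\theta = 0} is the inner wall) carries
#'     longitudinal strain
#'     \eqn{\varepsilon(\theta) = -\kappa (d/2) \cos\theta} (clamped to
#'     \eqn{|\varepsilon| \le 0.5}), and the modulated angle solves
#'     \eqn{\cos\alpha(\theta) = \cos(\alpha_{row})(1+\varepsilon)},
#'     clamped to [valid_angle_range()].
#' }
#'
#' Row placement solves the coupled system (row lengths depend on the
#' diameters at row centers, which depend on placement) by fixed-point
#' iteration; the local diameter is capped at the nominal diameter (a
#' device cannot expand past nominal).
#'
#' @param spec an [fd_device()].
#' @param vessel a [vessel_model()].
#' @param distal_s arc-length position of the distal end of the device, mm.
#' @param n_theta number of circumferential samples per row (>= 8).
#' @return An object of class `fd_deployment` with per-row geometry
#'   (`rows`: `s_center`, `local_diameter`, `alpha_row`, `row_length`,
#'   `kappa`) and per-sample fields (`porosity`, `mesh_angle`, `expansion`
#'   as `M x n_theta` matrices; `theta` in degrees).
#' @examples
#' spec <- fd_presets("Pipeline")
#' tube <- synthetic_vessel(length = 40, base_radius = 2)$vessel
#' dep <- deploy(spec, tube)
#' summary(dep)
#' @export
deploy <- function(spec, vessel, distal_s = 0, n_theta = 16L) {
  stopifnot(inherits(spec, "fd_device"), inherits(vessel, "vessel_model"))
  if (n_theta < 8) stop("n_theta must be at least 8", call. = FALSE)
  L <- vessel_length(vessel)
  if (distal_s < 0 || distal_s >= L)
    stop("distal_s must lie inside the vessel [0, ", signif(L, 6), ")",
         call. = FALSE)
  M <- nominal_row_count(spec)
  rng <- valid_angle_range(spec)
  # smallest admissible diameter: alpha(d) >= alpha_min of the valid range
  d_min <- spec$phi_nom * sin(rng[1] * DEG) / sin(spec$alpha_nom * DEG)

  # fixed-point row placement
  len <- rep(2 * spec$S * cos(spec$alpha_nom * DEG), M)
  centers <- distal_s + cumsum(len) - len / 2
  for (iter in 1:100) {
    cl <- pmin(centers, L)
    d <- pmin(diameter_at(vessel, cl), spec$phi_nom)
    if (any(d < d_min)) {
      i <- which(d < d_min)[1]
      stop(sprintf(paste0("vessel diameter %.3f mm at s = %.2f mm is below the ",
                          "smallest admissible diameter %.3f mm for device '%s' ",
                          "(braid fully closed)"),
                   d[i], cl[i], d_min, spec$brand_label), call. = FALSE)
    }
    alpha <- halfangle_at_diameter(spec, d)
    new_len <- 2 * spec$S * cos(alpha * DEG)
    ends <- distal_s + cumsum(new_len)
    new_centers <- ends - new_len / 2
    delta <- max(abs(new_centers - centers))
    centers <- new_centers; len <- new_len
    if (delta < 1e-10) break
  }
  if (centers[M] + len[M] / 2 > L + 1e-9) {
    placed <- sum(centers + len / 2 <= L + 1e-9)
    stop(sprintf(paste0("device '%s' overruns the vessel: only %d of %d rows ",
                        "fit between s = %.2f and the proximal end at %.2f mm"),
                 spec$brand_label, placed, M, distal_s, L), call. = FALSE)
  }
  d <- pmin(diameter_at(vessel, centers), spec$phi_nom)
  alpha_row <- halfangle_at_diameter(spec, d)

  cf <- .curvature_field(vessel)
  i <- findInterval(centers, vessel$s, all.inside = TRUE)
  i <- ifelse(centers - vessel$s[i] > vessel$s[i + 1] - centers, i + 1L, i)
  kappa <- cf$kappa[i]

  theta <- seq(0, 360, length.out = n_theta + 1L)[-(n_theta + 1L)]
  # strain, M x n_theta; theta = 0 is the inner wall (curvature normal)
  eps <- outer(-kappa * d / 2, cos(theta * DEG))
  eps <- pmin(pmax(eps, -0.5), 0.5)
  cosA <- cos(alpha_row * DEG) * (1 + eps)
  cosA <- pmin(pmax(cosA, cos(rng[2] * DEG)), cos(rng[1] * DEG))
  alpha_theta <- acos(cosA) / DEG
  porosity <- matrix(cell_porosity(spec$S, spec$omega, as.vector(alpha_theta)),
                     nrow = M)
  structure(list(
    spec = spec,
    vessel_name = vessel$name,
    distal_s = distal_s,
    rows = data.frame(s_center = centers, local_diameter = d,
                      alpha_row = alpha_row, row_length = len, kappa = kappa),
    theta = theta,
    porosity = porosity,
    mesh_angle = 2 * alpha_theta,
    expansion = matrix(100 * d / spec$phi_nom, nrow = M, ncol = n_theta)
  ), class = "fd_deployment")
}

#' Deployed (foreshortened) length of a device
#'
#' Sum of the per-row longitudinal lengths \eqn{2 S \cos(\alpha_{row})}.
#' Equals the nominal length (within one row's rounding) when the device is
#' everywhere at nominal expansion and grows as the vessel narrows.
#'
#' @param dev an [deploy()] result.
#' @return Length in mm.
#' @export
deployed_length <- function(dev) {
  stopifnot(inherits(dev, "fd_deployment"))
  sum(dev$rows$row_length)
}

#' Summarise the mesh fields over the aneurysm region
#'
#' Mean and population standard deviation of porosity, mesh angle
#' (\eqn{2\alpha}) and expansion over all circumferential samples of the
#' rows whose centers fall in the half-open interval of `region`.
#'
#' @param dev an [deploy()] result.
#' @param region an [aneurysm_region()].
#' @return An object of class `mesh_summary`: `porosity_mean`,
#'   `porosity_sd`, `angle_mean`, `angle_sd`, `expansion_mean`,
#'   `expansion_sd`, `n_points`.
#' @export
region_summary <- function(dev, region) {
  stopifnot(inherits(dev, "fd_deployment"), inherits(region, "aneurysm_region"))
  sel <- dev$rows$s_center >= region$s_start & dev$rows$s_center < region$s_end
  if (!any(sel))
    stop(sprintf("no device row center falls in the aneurysm region [%.2f, %.2f) mm",
                 region$s_start, region$s_end), call. = FALSE)
  pop <- function(x) {
    m <- mean(x)
    c(mean = m, sd = sqrt(mean((x - m)^2)))
  }
  p <- pop(dev$porosity[sel, , drop = FALSE])
  a <- pop(dev$mesh_angle[sel, , drop = FALSE])
  e <- pop(dev$expansion[sel, , drop = FALSE])
  structure(list(porosity_mean = unname(p["mean"]), porosity_sd = unname(p["sd"]),
                 angle_mean = unname(a["mean"]), angle_sd = unname(a["sd"]),
                 expansion_mean = unname(e["mean"]), expansion_sd = unname(e["sd"]),
                 n_points = sum(sel) * length(dev$theta)),
            class = "mesh_summary")
}

#' @export
print.mesh_summary <- function(x, ...) {
  cat(sprintf("Mesh summary over %d samples:\n", x$n_points))
  cat(sprintf("  porosity  %.3f (SD %.3f)\n", x$porosity_mean, x$porosity_sd))
  cat(sprintf("  mesh angle %.1f deg (SD %.1f)\n", x$angle_mean, x$angle_sd))
  cat(sprintf("  expansion %.1f%% (SD %.1f)\n", x$expansion_mean, x$expansion_sd))
  invisible(x)
}

#' @export
print.fd_deployment <- function(x, ...) {
  cat("Deployed '", x$spec$brand_label, "' in '", x$vessel_name, "': ",
      nrow(x$rows), " rows x ", length(x$theta), " samples\n", sep = "")
  cat(sprintf("  distal s %.2f mm, deployed length %.2f mm (nominal %.1f mm)\n",
              x$distal_s, deployed_length(x), x$spec$L_nom))
  invisible(x)
}

#' @export
summary.fd_deployment <- function(object, ...) {
  cat("Deployment of '", object$spec$brand_label, "' into '",
      object$vessel_name, "'\n", sep = "")
  cat(sprintf("  rows %d, deployed length %.2f mm (nominal %.1f mm)\n",
              nrow(object$rows), deployed_length(object), object$spec$L_nom))
  fmt <- function(lbl, m, u = "") {
    cat(sprintf("  %-10s mean %.3f%s, range [%.3f, %.3f]\n", lbl, mean(m), u,
                min(m), max(m)))
  }
  fmt("porosity", object$porosity)
  fmt("mesh angle", object$mesh_angle, " deg")
  fmt("expansion", object$expansion, " %")
  invisible(object)
}

#' Porosity field map of a deployment
#'
#' Image of the porosity field over arc length and circumferential angle
#' (theta = 0 / 360 is the inner wall of a bend).
#'
#' @param x an [deploy()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.fd_deployment <- function(x, ...) {
  graphics::image(x$rows$s_center, x$theta, x$porosity,
                  xlab = "arc length s (mm)", ylab = "theta (deg)",
                  main = paste("FD porosity:", x$spec$brand_label),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Per-sample field table of a deployment
#'
#' Deterministic row-major (rows by ascending arc length, then theta
#' ascending) long-format table of the deployed mesh fields, the schema
#' used by the field CSV export.
#'
#' @param x an [deploy()] result.
#' @param ... unused.
#' @return A data.frame with columns `s_mm`, `theta_deg`, `porosity`,
#'   `coverage`, `mesh_angle_deg`, `expansion_pct`.
#' @export
as.data.frame.fd_deployment <- function(x, ...) {
  M <- nrow(x$rows); K <- length(x$theta)
  data.frame(
    s_mm = rep(x$rows$s_center, each = K),
    theta_deg = rep(x$theta, times = M),
    porosity = as.vector(t(x$porosity)),
    coverage = 1 - as.vector(t(x$porosity)),
    mesh_angle_deg = as.vector(t(x$mesh_angle)),
    expansion_pct = as.vector(t(x$expansion))
  )
}
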