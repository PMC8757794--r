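#' Centerline vessel model
#'
#' A vessel is represented by ordered centerline samples: arc length `s`
#' (mm, starting at 0 at the distal end by convention), 3D position (mm)
#' and lumen radius (mm). Positions must be consistent with the stated arc
#' lengths and radii strictly positive.
#'
#' @param s numeric vector of arc lengths, strictly increasing from 0.
#' @param xyz numeric matrix (length(s) x 3) of centerline positions, mm.
#' @param radius numeric vector of lumen radii, mm, all positive.
#' @param name optional label.
#' @return An object of class `vessel_model`.
#' @export
vessel_model <- function(s, xyz, radius, name = "vessel") {
  xyz <- as.matrix(xyz)
  if (length(s) < 4L) stop("a vessel needs at least 4 samples", call. = FALSE)
  if (ncol(xyz) != 3L || nrow(xyz) != length(s))
    stop("xyz must be a length(s) x 3 matrix", call. = FALSE)
  if (length(radius) != length(s))
    stop("radius must match s in length", call. = FALSE)
  if (any(!is.finite(s)) || any(!is.finite(xyz)) || any(!is.finite(radius)))
    stop("non-finite values in vessel samples", call. = FALSE)
  if (any(diff(s) <= 0)) {
    i <- which(diff(s) <= 0)[1] + 1L
    stop("arc length must be strictly increasing; violation at sample ", i,
         call. = FALSE)
  }
  if (any(radius <= 0)) {
    i <- which(radius <= 0)[1]
    stop("radius must be positive; violation at sample ", i, call. = FALSE)
  }
  structure(list(s = as.numeric(s) - s[1], xyz = unname(xyz),
                 radius = as.numeric(radius), name = name),
            class = "vessel_model")
}

#' @export
print.vessel_model <- function(x, ...) {
  cat("Vessel centerline '", x$name, "': ", length(x$s), " samples, length ",
      sprintf("%.2f", vessel_length(x)), " mm, radius ",
      sprintf("%.2f-%.2f", min(x$radius), max(x$radius)), " mm\n", sep = "")
  invisible(x)
}

#' Total centerline length of a vessel
#' @param vessel a [vessel_model()].
#' @return Length in mm.
#' @export
vessel_length <- function(vessel) {
  stopifnot(inherits(vessel, "vessel_model"))
  vessel$s[length(vessel$s)]
}

#' Aneurysm neck region on the centerline
#'
#' The aneurysm region is the half-open arc-length interval
#' `[s_start, s_end)` covering the neck along the parent vessel; mesh
#' summaries ([region_summary()]) are taken over all device samples whose
#' row centers fall inside it.
#'
#' @param s_start,s_end interval bounds in mm, `0 <= s_start < s_end`.
#' @return An object of class `aneurysm_region`.
#' @export
aneurysm_region <- function(s_start, s_end) {
  if (!(s_start >= 0 && s_start < s_end))
    stop("need 0 <= s_start < s_end; got [", s_start, ", ", s_end, ")",
         call. = FALSE)
  structure(list(s_start = s_start, s_end = s_end), class = "aneurysm_region")
}

#' Aneurysm morphology descriptors
#'
#' Scalar morphology of a sidewall aneurysm: depth and width of the sac
#' (mm), sac volume (mm^3) and maximum/minimum neck diameter (mm). These
#' are the inputs from which the MAAI morphology index is built
#' ([fit_maai()]).
#'
#' @param depth,width sac depth and width, mm.
#' @param volume sac volume, mm^3.
#' @param neck_max,neck_min maximum and minimum neck diameter, mm.
#' @return An object of class `aneurysm_morphology` (a named list).
#' @export
aneurysm_morphology <- function(depth, width, volume, neck_max, neck_min) {
  v <- c(depth = depth, width = width, volume = volume,
         neck_max = neck_max, neck_min = neck_min)
  if (any(v <= 0)) stop("all morphology descriptors must be positive",
                        call. = FALSE)
  if (neck_min > neck_max)
    stop("neck_min must not exceed neck_max", call. = FALSE)
  structure(as.list(v), class = "aneurysm_morphology")
}

#' Read / write a centerline CSV
#'
#' The file format is a plain CSV with header
#' `s_mm,x_mm,y_mm,z_mm,radius_mm`. Malformed rows, non-monotone arc length
#' and non-positive radii are reported with their row number.
#'
#' @param path file path.
#' @param name label to attach to the model.
#' @return `read_centerline()` returns a [vessel_model()];
#'   `write_centerline()` returns `path` invisibly.
#' @export
read_centerline <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("centerline file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("s_mm", "x_mm", "y_mm", "z_mm", "radius_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centerline CSV '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("malformed centerline row ", bad[1], " in '", path, "'",
         call. = FALSE)
  if (any(df$radius_mm <= 0))
    stop("non-positive radius at row ", which(df$radius_mm <= 0)[1],
         " of '", path, "'", call. = FALSE)
  if (any(diff(df$s_mm) <= 0))
    stop("arc length not strictly increasing at row ",
         which(diff(df$s_mm) <= 0)[1] + 1L, " of '", path, "'", call. = FALSE)
  vessel_model(df$s_mm, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
               df$radius_mm, name = name)
}

#' @rdname read_centerline
#' @param vessel a [vessel_model()].
#' @export
write_centerline <- function(vessel, path) {
  stopifnot(inherits(vessel, "vessel_model"))
  df <- data.frame(s_mm = vessel$s, x_mm = vessel$xyz[, 1],
                   y_mm = vessel$xyz[, 2], z_mm = vessel$xyz[, 3],
                   radius_mm = vessel$radius)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a centerline at uniform arc-length spacing
#'
#' Positions and radii are linearly interpolated on a uniform grid from 0
#' to the total length; both endpoints are preserved.
#'
#' @param vessel a [vessel_model()].
#' @param ds target spacing, mm; `0 < ds < vessel_length(vessel)`.
#' @return A resampled [vessel_model()].
#' @export
resample_centerline <- function(vessel, ds) {
  stopifnot(inherits(vessel, "vessel_model"))
  L <- vessel_length(vessel)
  if (!(ds > 0 && ds < L))
    stop("ds must be in (0, ", signif(L, 6), ") mm", call. = FALSE)
  n <- max(2L, ceiling(L / ds) + 1L)
  grid <- seq(0, L, length.out = n)
  xyz <- cbind(stats::approx(vessel$s, vessel$xyz[, 1], grid)$y,
               stats::approx(vessel$s, vessel$xyz[, 2], grid)$y,
               stats::approx(vessel$s, vessel$xyz[, 3], grid)$y)
  vessel_model(grid, xyz, stats::approx(vessel$s, vessel$radius, grid)$y,
               name = vessel$name)
}

#' Lumen diameter at an arc-length position
#'
#' Twice the linearly interpolated radius; positions outside the sampled
#' range are clamped to the nearest endpoint.
#'
#' @param vessel a [vessel_model()].
#' @param s arc-length position(s), mm.
#' @return Diameter(s), mm.
#' @export
diameter_at <- function(vessel, s) {
  stopifnot(inherits(vessel, "vessel_model"))
  s <- pmin(pmax(s, 0), vessel_length(vessel))
  2 * stats::approx(vessel$s, vessel$radius, s)$y
}

# Per-sample curvature vector field: discrete derivatives of position with
# respect to arc length (central differences on a possibly non-uniform grid).
# Returns kappa (1/mm) and the unit normal (toward the curvature center) at
# every sample; straight samples (kappa < tol) get a fixed, documented
# reference normal so results are reproducible.
.curvature_field <- function(vessel, tol = 1e-8) {
  s <- vessel$s; P <- vessel$xyz; n <- length(s)
  d1 <- matrix(0, n, 3); d2 <- matrix(0, n, 3)
  for (k in 1:3) {
    p <- P[, k]
    # non-uniform central first/second differences; one-sided at the ends
    h1 <- s[2:(n - 1)] - s[1:(n - 2)]
    h2 <- s[3:n] - s[2:(n - 1)]
    d1[2:(n - 1), k] <- (p[3:n] * h1^2 + (h2^2 - h1^2) * p[2:(n - 1)] -
                           p[1:(n - 2)] * h2^2) / (h1 * h2 * (h1 + h2))
    d2[2:(n - 1), k] <- 2 * (p[3:n] * h1 - (h1 + h2) * p[2:(n - 1)] +
                               p[1:(n - 2)] * h2) / (h1 * h2 * (h1 + h2))
    d1[1, k] <- (p[2] - p[1]) / (s[2] - s[1])
    d1[n, k] <- (p[n] - p[n - 1]) / (s[n] - s[n - 1])
    d2[1, k] <- d2[2, k]; d2[n, k] <- d2[n - 1, k]
  }
  t_norm <- sqrt(rowSums(d1^2))
  t_unit <- d1 / pmax(t_norm, 1e-300)
  # curvature vector: component of d2 orthogonal to the tangent, / |d1|^2
  proj <- rowSums(d2 * t_unit)
  kvec <- (d2 - proj * t_unit) / pmax(t_norm, 1e-300)^2
  kappa <- sqrt(rowSums(kvec^2))
  normal <- kvec / pmax(kappa, 1e-300)
  straight <- kappa < tol
  if (any(straight)) {
    # fixed reference: global +z projected orthogonal to the tangent,
    # falling back to +y when the tangent is parallel to z
    for (i in which(straight)) {
      ref <- c(0, 0, 1)
      v <- ref - sum(ref * t_unit[i, ]) * t_unit[i, ]
      if (sqrt(sum(v^2)) < 1e-6) {
        ref <- c(0, 1, 0)
        v <- ref - sum(ref * t_unit[i, ]) * t_unit[i, ]
      }
      normal[i, ] <- v / sqrt(sum(v^2))
      kappa[i] <- 0
    }
  }
  list(kappa = kappa, normal = normal, tangent = t_unit)
}

#' Centerline curvature at an arc-length position
#'
#' Discrete estimate of the centerline curvature \eqn{\kappa} and the unit
#' normal pointing toward the curvature center, from second differences of
#' the sampled positions. For straight segments (\eqn{\kappa} below
#' `1e-8` per mm) the curvature is reported as 0 with a fixed reference
#' normal (the global z axis projected orthogonal to the tangent) so that
#' downstream results are reproducible.
#'
#' @param vessel a [vessel_model()].
#' @param s arc-length position, mm (clamped to the sampled range).
#' @return A list with `kappa` (1/mm) and `normal` (unit 3-vector).
#' @export
curvature_at <- function(vessel, s) {
  stopifnot(inherits(vessel, "vessel_model"))
  cf <- .curvature_field(vessel)
  s <- pmin(pmax(s, 0), vessel_length(vessel))
  i <- findInterval(s, vessel$s, all.inside = TRUE)
  # nearest-sample lookup (curvature is a second-difference quantity;
  # interpolating the normal across an inflection would be ill-defined)
  i <- ifelse(s - vessel$s[i] > vessel$s[i + 1] - s, i + 1L, i)
  if (length(s) == 1L)
    list(kappa = cf$kappa[i], normal = cf$normal[i, ])
  else
    list(kappa = cf$kappa[i], normal = cf$normal[i, , drop = FALSE])
}
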