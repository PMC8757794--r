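# Independent oracles and small fixtures shared across the suite.

# Monte-Carlo rasterisation oracle for the unit-cell metal fraction:
# pixel-counts the union of the two omega-wide wire strips over the
# rhombic cell. Points are laid out on a midpoint grid in lattice
# coordinates (a, b) along the two strut directions; the affine map to
# physical space preserves uniformity, and the perpendicular spacing of
# each strip family is the cell area / strut length = S * sin(2 alpha).
rasterize_metal_fraction <- function(S, omega, alpha_deg, n = 2048L) {
  spacing <- S * sin(2 * alpha_deg * pi / 180)
  g <- (seq_len(n) - 0.5) / n
  dist_frac <- pmin(g, 1 - g)          # fractional distance to nearest line
  in_strip <- dist_frac * spacing < omega / 2
  mean(outer(in_strip, in_strip, "|"))
}

# Brute-force grid-search maximiser of the Bernoulli log-likelihood for a
# two-parameter (intercept + slope) logit model.
grid_logit_mle <- function(y, x, b0_range, b1_range, n_grid = 81L) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  for (pass in 1:9) {
    L <- outer(b0s, b1s, Vectorize(ll))
    i <- which(L == max(L), arr.ind = TRUE)[1, ]
    w0 <- diff(range(b0s)) / 4; w1 <- diff(range(b1s)) / 4
    best <- c(b0s[i[1]], b1s[i[2]])
    b0s <- seq(best[1] - w0, best[1] + w0, length.out = n_grid)
    b1s <- seq(best[2] - w1, best[2] + w1, length.out = n_grid)
  }
  best
}

# straight constant tube of the given diameter
straight_tube <- function(diameter, length = 50, ds = 0.25) {
  synthetic_vessel(length, diameter / 2, ds = ds)$vessel
}

# equicorrelated standard-normal draws via a one-factor model
equicorr_normal <- function(n, p, rho) {
  f <- rnorm(n)
  sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

# simple reference device used across geometry tests
ref_device <- function(alpha_nom = 50, phi = 4, L = 20)
  fd_device("ref", phi_nom = phi, L_nom = L, n_wires = 48, S = 0.5,
            omega = 0.05, alpha_nom = alpha_nom)
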