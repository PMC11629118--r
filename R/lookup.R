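#' Precompute a forward-model lookup table
#'
#' Simulates the forward model on a log-spaced grid of optical properties
#' at fixed geometry and assumptions.  The table initializes the inverse
#' search; every node is a full [simulate_rt()] run sharing one seed
#' (common random numbers across nodes, which keeps the tabulated
#' response surface smooth).
#'
#' @param thickness Tissue slab thickness, mm.
#' @param g,n Assumed anisotropy factor and tissue refractive index.
#' @param mua_range,musp_range Grid bounds, mm^-1.  Defaults cover soft
#'   tissue in the visible range with margin.
#' @param n_mua,n_musp Number of log-spaced nodes per axis (>= 2 each).
#' @param n_photons Photons per node.
#' @param seed Engine seed shared by all nodes.
#' @param beam,detector,glass Measurement geometry, as in [simulate_rt()]
#'   and [build_slab()].
#' @return An object of class `rt_lookup` holding `Rd` and `Tt` matrices
#'   (rows: mu_a nodes, columns: mu_sp nodes), the grids, and metadata.
#' @export
build_lookup <- function(thickness, g = 0.9, n = 1.4,
                         mua_range = c(0.01, 5), musp_range = c(0.1, 10),
                         n_mua = 8, n_musp = 8, n_photons = 1e5, seed = 1,
                         beam = beam_geometry(),
                         detector = detector_geometry(),
                         glass = glass_slide()) {
  if (n_mua < 2 || n_musp < 2)
    stop("lookup grid needs at least 2 nodes per axis", call. = FALSE)
  if (any(mua_range <= 0) || any(musp_range <= 0))
    stop("grid bounds must be positive", call. = FALSE)
  mua_grid <- exp(seq(log(mua_range[1]), log(mua_range[2]), length.out = n_mua))
  musp_grid <- exp(seq(log(musp_range[1]), log(musp_range[2]),
                       length.out = n_musp))
  Rd <- matrix(NA_real_, n_mua, n_musp)
  Tt <- matrix(NA_real_, n_mua, n_musp)
  for (i in seq_len(n_mua)) {
    for (j in seq_len(n_musp)) {
      st <- build_slab(mua_grid[i], musp_grid[j], thickness, g, n, glass)
      r <- simulate_rt(st, beam, detector, n_photons, seed)
      Rd[i, j] <- r$Rd
      Tt[i, j] <- r$Tt
    }
  }
  structure(list(mua_grid = mua_grid, musp_grid = musp_grid, Rd = Rd,
                 Tt = Tt, thickness = thickness, g = g, n = n,
                 n_photons = n_photons, seed = seed, beam = beam,
                 detector = detector, glass = glass),
            class = "rt_lookup")
}

#' @export
print.rt_lookup <- function(x, ...) {
  cat(sprintf(
    "Forward-model lookup: %dx%d nodes, mu_a [%g, %g], mu_sp [%g, %g] mm^-1\n",
    length(x$mua_grid), length(x$musp_grid), min(x$mua_grid),
    max(x$mua_grid), min(x$musp_grid), max(x$musp_grid)))
  cat(sprintf("  thickness %g mm, g = %g, n = %g, %g photons/node, seed %d\n",
              x$thickness, x$g, x$n, x$n_photons, x$seed))
  invisible(x)
}

# bilinear interpolation of the tabulated (Rd, Tt) in log-property space;
# queries are clamped to the grid hull.
lut_interpolate <- function(lut, mu_a, mu_sp) {
  lx <- log(pmin(pmax(mu_a, min(lut$mua_grid)), max(lut$mua_grid)))
  ly <- log(pmin(pmax(mu_sp, min(lut$musp_grid)), max(lut$musp_grid)))
  gx <- log(lut$mua_grid)
  gy <- log(lut$musp_grid)
  i <- pmin(pmax(findInterval(lx, gx), 1), length(gx) - 1)
  j <- pmin(pmax(findInterval(ly, gy), 1), length(gy) - 1)
  tx <- (lx - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (ly - gy[j]) / (gy[j + 1] - gy[j])
  blend <- function(M) {
    (1 - tx) * (1 - ty) * M[cbind(i, j)] +
      tx * (1 - ty) * M[cbind(i + 1, j)] +
      (1 - tx) * ty * M[cbind(i, j + 1)] +
      tx * ty * M[cbind(i + 1, j + 1)]
  }
  list(Rd = blend(lut$Rd), Tt = blend(lut$Tt))
}

# grid-search initialization: minimize the combined relative misfit over a
# refined (interpolated) grid and return the best (mu_a, mu_sp)
lut_init <- function(lut, Rd, Tt, refine = 41) {
  ma <- exp(seq(log(min(lut$mua_grid)), log(max(lut$mua_grid)),
                length.out = refine))
  ms <- exp(seq(log(min(lut$musp_grid)), log(max(lut$musp_grid)),
                length.out = refine))
  gg <- expand.grid(mu_a = ma, mu_sp = ms)
  p <- lut_interpolate(lut, gg$mu_a, gg$mu_sp)
  f <- ((p$Rd - Rd) / max(Rd, 1e-4))^2 + ((p$Tt - Tt) / max(Tt, 1e-4))^2
  k <- which.min(f)
  c(mu_a = gg$mu_a[k], mu_sp = gg$mu_sp[k])
}
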