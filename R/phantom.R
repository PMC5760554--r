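#' Synthetic labeled structures
#'
#' Generates emitter positions on idealized 3D structures mimicking common
#' immunolabeled targets: a spherical shell (nuclear lamina), a hollow
#' cylinder (mitochondrial outer membrane), a field of fiducial beads, or an
#' explicit point list. Emitters are sampled uniformly on the surface with a
#' Poisson-distributed total count (`area x density`) and Gaussian radial
#' jitter emulating the label/linker shell thickness.
#'
#' @param kind One of `"lamina_shell"`, `"mito_cylinder"`, `"bead_field"`,
#'   `"points"`.
#' @param center_um Structure center `(x, y, z)` in um.
#' @param radius_um Shell or cylinder radius in um (> 0).
#' @param length_um Cylinder length in um.
#' @param axis Cylinder axis direction (3-vector, normalized internally).
#' @param thickness_nm Label shell thickness: radial jitter is Gaussian with
#'   sd `thickness_nm / 2.355` so the radial profile FWHM equals the
#'   thickness.
#' @param density_um2 Emitters per um^2 of surface.
#' @param n Bead count (`bead_field`).
#' @param fov_um Lateral extent `(x, y)` for bead placement in um.
#' @param z_um Bead heights in um (`bead_field`; recycled), or ignored.
#' @param positions `data.frame(x_nm, y_nm, z_nm)` for `kind = "points"`.
#' @param seed Integer seed; the same seed reproduces the phantom exactly.
#' @return A `phantom`: `data.frame(x_nm, y_nm, z_nm)` with attributes
#'   `kind` and the geometry parameters.
#' @export
make_phantom <- function(kind = c("lamina_shell", "mito_cylinder",
                                  "bead_field", "points"),
                         center_um = c(0, 0, 0), radius_um = 2,
                         length_um = 2, axis = c(1, 0, 0),
                         thickness_nm = 0, density_um2 = 100,
                         n = 1, fov_um = c(15, 15), z_um = 0,
                         positions = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  jitter_r <- thickness_nm / (2 * sqrt(2 * log(2)))
  out <- switch(kind,
    lamina_shell = {
      if (radius_um <= 0) stop("degenerate geometry: zero radius")
      area <- 4 * pi * radius_um^2
      m <- stats::rpois(1, area * density_um2)
      dir <- matrix(stats::rnorm(3 * m), m, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      r_nm <- radius_um * 1000 + stats::rnorm(m, 0, jitter_r)
      data.frame(x_nm = center_um[1] * 1000 + dir[, 1] * r_nm,
                 y_nm = center_um[2] * 1000 + dir[, 2] * r_nm,
                 z_nm = center_um[3] * 1000 + dir[, 3] * r_nm)
    },
    mito_cylinder = {
      if (radius_um <= 0 || length_um <= 0)
        stop("degenerate geometry: zero radius or length")
      area <- 2 * pi * radius_um * length_um
      m <- stats::rpois(1, area * density_um2)
      a <- axis / sqrt(sum(axis^2))
      ## orthonormal frame around the axis
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a[2] * e1[3] - a[3] * e1[2],
              a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      t_nm <- stats::runif(m, -length_um / 2, length_um / 2) * 1000
      th <- stats::runif(m, 0, 2 * pi)
      r_nm <- radius_um * 1000 + stats::rnorm(m, 0, jitter_r)
      p <- outer(t_nm, a) + outer(r_nm * cos(th), e1) + outer(r_nm * sin(th), e2)
      data.frame(x_nm = center_um[1] * 1000 + p[, 1],
                 y_nm = center_um[2] * 1000 + p[, 2],
                 z_nm = center_um[3] * 1000 + p[, 3])
    },
    bead_field = {
      data.frame(x_nm = stats::runif(n, -fov_um[1] / 2, fov_um[1] / 2) * 1000,
                 y_nm = stats::runif(n, -fov_um[2] / 2, fov_um[2] / 2) * 1000,
                 z_nm = rep_len(z_um, n) * 1000)
    },
    points = {
      stopifnot(is.data.frame(positions),
                all(c("x_nm", "y_nm", "z_nm") %in% names(positions)))
      positions[c("x_nm", "y_nm", "z_nm")]
    })
  structure(out, kind = kind, center_um = center_um, radius_um = radius_um,
            thickness_nm = thickness_nm, density_um2 = density_um2,
            class = c("phantom", "data.frame"))
}
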