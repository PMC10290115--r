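#' Three-section geometry of an aspirated red blood cell
#'
#' An aspirated cell is modelled as three sections: (I) a hemispherical cap
#' of pipette radius \code{a} at the tip of the tongue, (II) a cylinder of
#' radius \code{a} and length \code{l} inside the pipette, and (III) a
#' sphere of radius \code{r} outside the pipette with the spherical cap
#' subtended by the pipette mouth removed. All lengths in micrometre,
#' areas in square micrometre, volumes in cubic micrometre (1 fL = 1 um^3).
#'
#' @name aspiration-geometry
NULL

check_ar <- function(a, r) {
  if (any(a <= 0)) stop("pipette radius a must be > 0")
  if (any(r < a)) stop("cell radius r must be >= pipette radius a")
}

#' Section volumes of the three-section model
#'
#' V_I = (2/3) pi a^3 (hemispherical cap), V_II = pi a^2 l (cylinder),
#' V_III = (pi/3) (2 r^3 + (2 r^2 + a^2) sqrt(r^2 - a^2)) (truncated
#' sphere). The truncated-sphere expression is algebraically identical to
#' the full sphere volume minus the spherical-cap volume
#' pi h^2 (3r - h) / 3 with cap height h = r - sqrt(r^2 - a^2).
#'
#' @param a pipette inner radius (um), > 0.
#' @param r outside-sphere radius (um), >= a.
#' @param l cylindrical tongue length (um), >= 0.
#' @return Named numeric vector \code{c(V_I, V_II, V_III)} (um^3).
#' @export
section_volumes <- function(a, r, l) {
  check_ar(a, r)
  if (any(l < 0)) stop("tongue length l must be >= 0")
  c(V_I = 2 / 3 * pi * a^3,
    V_II = pi * a^2 * l,
    V_III = pi / 3 * (2 * r^3 + (2 * r^2 + a^2) * sqrt(r^2 - a^2)))
}

#' Section surface areas of the three-section model
#'
#' A_I = 2 pi a^2 (hemisphere), A_II = 2 pi a l (cylinder wall),
#' A_III = 2 pi r (r + sqrt(r^2 - a^2)) (truncated sphere, i.e. full
#' sphere minus the cap area 2 pi r h).
#'
#' @inheritParams section_volumes
#' @return Named numeric vector \code{c(A_I, A_II, A_III)} (um^2).
#' @export
section_areas <- function(a, r, l) {
  check_ar(a, r)
  if (any(l < 0)) stop("tongue length l must be >= 0")
  c(A_I = 2 * pi * a^2,
    A_II = 2 * pi * a * l,
    A_III = 2 * pi * r * (r + sqrt(r^2 - a^2)))
}

v3 <- function(a, r) pi / 3 * (2 * r^3 + (2 * r^2 + a^2) * sqrt(r^2 - a^2))
a3 <- function(a, r) 2 * pi * r * (r + sqrt(r^2 - a^2))

#' Solve the reference cell geometry from pipette radius
#'
#' The pipette radius is the only length that can be read accurately from
#' the images, so the outside radius \code{r} and tongue length \code{l}
#' are instead determined from the known red-blood-cell volume (90 fL) and
#' surface area (136 um^2): the area constraint is solved for \code{l} as a
#' function of \code{r} and substituted into the volume constraint, leaving
#' a one-dimensional root-finding problem in \code{r}, solved by bracketed
#' bisection/Brent iteration to 1e-12 um.
#'
#' @param a pipette inner radius (um). The typical pipette tip (inner
#'   diameter ~2.1 um) gives a = 1.05 um.
#' @param V_total cell volume (um^3); default 90.
#' @param A_total cell surface area (um^2); default 136.
#' @param r_max upper bracket for the outside radius (um).
#' @return A list of class \code{"aspirated_cell_geometry"} with elements
#'   \code{a}, \code{r}, \code{l}, \code{V_total}, \code{A_total} and the
#'   achieved residuals.
#' @examples
#' solve_reference_geometry(1.05)
#' @export
solve_reference_geometry <- function(a, V_total = 90, A_total = 136,
                                     r_max = 10) {
  stopifnot(a > 0, V_total > 0, A_total > 0)
  l_of_r <- function(r) (A_total - 2 * pi * a^2 - a3(a, r)) / (2 * pi * a)
  f <- function(r) 2 / 3 * pi * a^3 + pi * a^2 * l_of_r(r) + v3(a, r) - V_total
  lo <- a * (1 + 1e-6)
  if (f(lo) * f(r_max) > 0)
    stop(sprintf(paste0("no physical solution: volume residual has no sign",
                        " change on r in (%.4g, %.4g] (f(lo)=%.4g,",
                        " f(hi)=%.4g)"), lo, r_max, f(lo), f(r_max)))
  r <- stats::uniroot(f, c(lo, r_max), tol = 1e-12)$root
  l <- l_of_r(r)
  if (l < 0)
    stop("no physical solution: implied tongue length is negative")
  vres <- sum(section_volumes(a, r, l)) - V_total
  ares <- sum(section_areas(a, r, l)) - A_total
  structure(list(a = a, r = r, l = l, V_total = V_total, A_total = A_total,
                 volume_residual = vres, area_residual = ares),
            class = "aspirated_cell_geometry")
}

#' @export
print.aspirated_cell_geometry <- function(x, ...) {
  cat(sprintf(paste0("aspirated cell geometry: a = %.4g um, r = %.6g um,",
                     " l = %.6g um\n  V = %.6g um^3, A = %.6g um^2",
                     " (residuals %.2e, %.2e)\n"),
              x$a, x$r, x$l, x$V_total, x$A_total,
              x$volume_residual, x$area_residual))
  invisible(x)
}

#' Membrane-area change from a tongue displacement
#'
#' When illumination changes the membrane area, the interface in the
#' pipette moves by \code{delta_l} (positive = deeper into the pipette)
#' while the cell volume stays constant, so the volume of the outside
#' sphere must change by \code{-pi a^2 delta_l}. The new outside radius
#' \code{r_new} is found by one-dimensional root finding on the
#' truncated-sphere volume, and the new total area is
#' A_I + 2 pi a (l + delta_l) + A_III(r_new). The absolute area change is
#' the difference to the reference area, the relative change its percentage
#' of the reference area.
#'
#' @param geom an \code{\link{solve_reference_geometry}} result.
#' @param delta_l interface displacement (um); may be a vector.
#' @param legacy_area_prefactor logical; if \code{TRUE}, use the variant
#'   A_III,new = 2 pi r (r_new + sqrt(r_new^2 - a^2)) that keeps the old
#'   radius in the prefactor. The default \code{FALSE} uses the
#'   geometrically consistent truncated-sphere area
#'   2 pi r_new (r_new + sqrt(r_new^2 - a^2)).
#' @return A data frame with one row per displacement: \code{delta_l},
#'   \code{r_new}, \code{dA_abs} (um^2), \code{dA_rel} (percent), and the
#'   conserved-volume residual \code{V_residual}.
#' @examples
#' g <- solve_reference_geometry(1.058)
#' apply_tongue_displacement(g, 0.82)
#' @export
apply_tongue_displacement <- function(geom, delta_l,
                                      legacy_area_prefactor = FALSE) {
  stopifnot(inherits(geom, "aspirated_cell_geometry"))
  a <- geom$a
  one <- function(dl) {
    target <- v3(a, geom$r) - pi * a^2 * dl
    if (target <= 2 / 3 * pi * a^3)
      stop(sprintf("delta_l = %.4g um leaves no valid outside sphere", dl))
    f <- function(r) v3(a, r) - target
    lo <- a * (1 + 1e-9)
    hi <- max(geom$r * 2, 10)
    if (f(lo) > 0 || f(hi) < 0)
      stop(sprintf("delta_l = %.4g um admits no outside radius r_new > a", dl))
    r_new <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    pref <- if (legacy_area_prefactor) geom$r else r_new
    A_new <- 2 * pi * a^2 + 2 * pi * a * (geom$l + dl) +
      2 * pi * pref * (r_new + sqrt(r_new^2 - a^2))
    V_new <- 2 / 3 * pi * a^3 + pi * a^2 * (geom$l + dl) + v3(a, r_new)
    c(r_new = r_new, dA_abs = A_new - geom$A_total,
      V_residual = V_new - geom$V_total)
  }
  res <- t(vapply(delta_l, one, numeric(3)))
  out <- data.frame(delta_l = delta_l,
                    r_new = res[, "r_new"],
                    dA_abs = res[, "dA_abs"],
                    dA_rel = relative_area_change(res[, "dA_abs"],
                                                  geom$A_total),
                    V_residual = res[, "V_residual"])
  rownames(out) <- NULL
  out
}

#' Relative membrane-area change
#'
#' @param dA_abs absolute area change (um^2).
#' @param A_total reference surface area (um^2), default 136.
#' @return Relative change in percent: \code{100 * dA_abs / A_total}.
#' @examples
#' relative_area_change(2.9)  # ~2.1 percent
#' @export
relative_area_change <- function(dA_abs, A_total = 136) {
  stopifnot(A_total > 0)
  100 * dA_abs / A_total
}
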