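#' Ellipsoid model of a lacuna
#'
#' An ellipsoid is the shape model fitted to each lacuna: centre `c`, a
#' right-handed rotation matrix `R` whose *columns* are the principal axis
#' directions, and full axis lengths `L1 >= L2 >= L3` in micrometres. A point
#' `x` lies on the surface when `(x - c)' R A R' (x - c) = 1` with
#' `A = diag(1 / (L/2 + r)^2)` and `r = 0`; increasing `r` dilates the
#' ellipsoid isotropically by `r` along each semi-axis, which is how bounding
#' shells at a distance from the lacunar surface are generated analytically.
#'
#' @param center_um centre, micrometres (length 3).
#' @param lengths_um full axis lengths in micrometres, sorted descending
#'   internally; all > 0.
#' @param rotation 3x3 rotation matrix, columns = axis directions (defaults to
#'   identity). Made right-handed if needed.
#' @return object of class `lcn_ellipsoid`.
#' @examples
#' e <- ellipsoid(c(0, 0, 0), c(17.2, 9.4, 4.8))
#' e$lengths_um
#' @export
ellipsoid <- function(center_um, lengths_um, rotation = diag(3)) {
  stopifnot(length(center_um) == 3, length(lengths_um) == 3)
  if (any(lengths_um <= 0)) stop("axis lengths must be positive")
  o <- order(lengths_um, decreasing = TRUE)
  lengths_um <- as.numeric(lengths_um[o])
  rotation <- rotation[, o, drop = FALSE]
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("`rotation` must be orthonormal")
  rotation <- righthanded(rotation)
  structure(list(center_um = as.numeric(center_um),
                 lengths_um = lengths_um,
                 rotation = rotation),
            class = "lcn_ellipsoid")
}

#' @export
print.lcn_ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> L = %s um at (%s) um\n",
              paste(signif(x$lengths_um, 4), collapse = " x "),
              paste(signif(x$center_um, 3), collapse = ", ")))
  invisible(x)
}

# Quadratic form value of points against an ellipsoid dilated by r:
# q(x) = (x-c)' R A R' (x-c), A = diag(1/(L/2 + r)^2). q <= 1 inside.
# `pts` is an n x 3 matrix of coordinates in um.
ellipsoid_quadform <- function(e, pts, r_um = 0) {
  semi <- e$lengths_um / 2 + r_um
  d <- sweep(pts, 2, e$center_um)
  y <- d %*% e$rotation              # local coordinates along the axes
  (y[, 1] / semi[1])^2 + (y[, 2] / semi[2])^2 + (y[, 3] / semi[3])^2
}

# Analytic volume of an ellipsoid dilated by r (um^3).
ellipsoid_volume_um3 <- function(e, r_um = 0) {
  semi <- e$lengths_um / 2 + r_um
  4 / 3 * pi * prod(semi)
}

# Thomsen approximation to the ellipsoid surface area (um^2); relative error
# below ~1.1% for all aspect ratios. Used for analytic cross-checks.
ellipsoid_surface_um3 <- function(e, r_um = 0) {
  s <- e$lengths_um / 2 + r_um
  p <- 1.6075
  4 * pi * ((s[1]^p * s[2]^p + s[1]^p * s[3]^p + s[2]^p * s[3]^p) / 3)^(1 / p)
}

# Point on the (undilated) surface hit by the ray from the centre along unit
# direction u (world frame).
ellipsoid_surface_point <- function(e, u) {
  q <- ellipsoid_quadform(e, matrix(e$center_um + u, 1, 3))
  e$center_um + u / sqrt(q)
}
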