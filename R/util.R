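# Internal numerical utilities shared across modules.

# Connected-component labeling of a logical 3D array.
# Returns integer array; labels in raster-scan order of first voxels.
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  lab <- .cpp_label_components(as.logical(mask), as.integer(dim(mask)),
                               as.integer(connectivity))
  n <- attr(lab, "n_labels")
  lab <- array(lab, dim = dim(mask))
  attr(lab, "n_labels") <- n
  lab
}

# Exact Euclidean distance (voxel units) to the nearest TRUE voxel.
edt_voxels <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("edt of an empty mask is undefined")
  d2 <- .cpp_edt_squared(as.logical(mask), as.integer(dim(mask)))
  array(sqrt(d2), dim = dim(mask))
}

# Random rotation matrix (uniform via QR of a Gaussian matrix), det +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Ensure a rotation matrix is right-handed (det +1).
righthanded <- function(R) {
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# Eigenvalues of many symmetric 3x3 matrices at once, using the analytic
# trigonometric method (Smith 1961). Inputs are vectors of the six unique
# entries; returns a list of three vectors sorted ascending by value.
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  # r = det(M - q I) / (2 p^3), clamped to [-1, 1]
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)                  # largest
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)     # smallest
  e2 <- 3 * q - e1 - e3
  list(lo = e3, mid = e2, hi = e1)
}

# Shift an array by one voxel along an axis, replicating the edge slab.
shift_edge <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- seq_len(d[axis]) - by
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}
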