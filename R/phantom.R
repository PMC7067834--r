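#' Phantom generator configuration
#'
#' Default parameters emulate the tissue this package is designed for: human
#' cortical bone with ellipsoidal osteocyte lacunae of mean axis lengths
#' 17.2 x 9.4 x 4.8 um (close to 4:2:1 anisotropy), a lacunar number density
#' of ~3.2e4 per mm^3 (about 7 lacunae in a 61.44 um cubic field of view),
#' and ~80 primary canaliculi stemming from each lacuna with diameters in the
#' 200-500 nm range. Pores are dark and the mineralized matrix bright. Test
#' and example scenes override these knobs with smaller values for speed; the
#' defaults are the realistic operating point.
#'
#' @param domain_um cubic domain edge lengths (um), length 3.
#' @param n_lacunae number of lacunae to place (>= 0).
#' @param lacuna_axes_um mean full axis lengths L1 >= L2 >= L3 (um).
#' @param lacuna_axes_sd_um per-axis standard deviation of lengths (um).
#' @param random_orientation random lacuna orientations, or axis-aligned.
#' @param n_canaliculi canaliculi stemming from each lacuna.
#' @param canaliculi_radius_um tube radius (um); 0.15 um corresponds to a
#'   300 nm diameter, the middle of the reported physiological range.
#' @param canaliculi_length_um total arc length of each tube (um).
#' @param branch_at_um arc-length distances (um) from the lacunar surface at
#'   which every tube bifurcates into two children; `NULL` for straight tubes.
#' @param branch_angle_deg half-angle between child tubes at a bifurcation.
#' @param tube_directions `"even"` for near-uniform (Fibonacci lattice)
#'   directions, `"random"` for isotropic random directions.
#' @param matrix_gray,pore_gray gray levels of matrix and pores
#'   (`pore_gray < matrix_gray`).
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   applied at rasterization, in gray units.
#' @param salt_pepper_fraction fraction of voxels replaced by impulse
#'   (speckle) noise at rasterization; exercises the median filter.
#' @param max_attempts rejection-sampling attempts per lacuna before failing.
#' @return a list of class `lcn_phantom_config`.
#' @export
phantom_config <- function(domain_um = c(61.44, 61.44, 61.44),
                           n_lacunae = 7,
                           lacuna_axes_um = c(17.2, 9.4, 4.8),
                           lacuna_axes_sd_um = c(1.8, 1.1, 0.7),
                           random_orientation = TRUE,
                           n_canaliculi = 80,
                           canaliculi_radius_um = 0.15,
                           canaliculi_length_um = 15,
                           branch_at_um = NULL,
                           branch_angle_deg = 25,
                           tube_directions = c("even", "random"),
                           matrix_gray = 1,
                           pore_gray = 0,
                           noise_sigma = 0.1,
                           salt_pepper_fraction = 0,
                           max_attempts = 2000) {
  if (pore_gray >= matrix_gray) stop("pores must be darker than matrix")
  if (n_lacunae < 0) stop("n_lacunae must be >= 0")
  if (any(domain_um <= 0)) stop("domain extent must be positive")
  cfg <- list(domain_um = rep(domain_um, length.out = 3),
              n_lacunae = as.integer(n_lacunae),
              lacuna_axes_um = sort(rep(lacuna_axes_um, length.out = 3),
                                    decreasing = TRUE),
              lacuna_axes_sd_um = rep(lacuna_axes_sd_um, length.out = 3),
              random_orientation = isTRUE(random_orientation),
              n_canaliculi = as.integer(n_canaliculi),
              canaliculi_radius_um = canaliculi_radius_um,
              canaliculi_length_um = canaliculi_length_um,
              branch_at_um = branch_at_um,
              branch_angle_deg = branch_angle_deg,
              tube_directions = match.arg(tube_directions),
              matrix_gray = matrix_gray,
              pore_gray = pore_gray,
              noise_sigma = noise_sigma,
              salt_pepper_fraction = salt_pepper_fraction,
              max_attempts = as.integer(max_attempts))
  class(cfg) <- "lcn_phantom_config"
  cfg
}

# Near-uniform directions on the sphere (Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Rotate unit vector u by angle theta around unit axis a (Rodrigues).
rotate_about <- function(u, a, theta) {
  u * cos(theta) + pracma_cross(a, u) * sin(theta) + a * sum(a * u) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Build a synthetic ground-truth LCN scene
#'
#' Places non-overlapping ellipsoidal lacunae in the domain by rejection
#' sampling (bounding-sphere overlap test) and grows canalicular tubes from
#' each lacunar surface: capsules around polylines, radially outward, with
#' optional bifurcations at prescribed arc lengths. The scene is continuous
#' (micrometre coordinates) and can be rasterized at any voxel size. The
#' per-lacuna tube counts and branch distances are recorded as ground truth.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; the same (config, seed) gives a bit-identical
#'   scene.
#' @return object of class `lcn_scene` with fields `lacunae` (list of
#'   [ellipsoid()]), `canaliculi` (list of tube segments with vertices, radius,
#'   parent lacuna and branch depth), gray/noise settings, `domain_um` and
#'   `rng_seed`.
#' @export
build_scene <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "lcn_phantom_config"))
  set.seed(seed)
  lacunae <- list()
  if (config$n_lacunae > 0) {
    for (i in seq_len(config$n_lacunae)) {
      placed <- FALSE
      for (att in seq_len(config$max_attempts)) {
        L <- sort(abs(rnorm(3, config$lacuna_axes_um, config$lacuna_axes_sd_um)),
                  decreasing = TRUE)
        L <- pmax(L, 0.1)
        margin <- L[1] / 2 + if (is.null(config$branch_at_um)) 0 else 0
        lo <- margin
        hi <- config$domain_um - margin
        if (any(hi <= lo))
          stop(sprintf("infeasible packing: lacuna %d does not fit the domain (placed %d)",
                       i, length(lacunae)))
        ctr <- runif(3, lo, hi)
        ok <- TRUE
        for (e in lacunae) {
          if (sqrt(sum((ctr - e$center_um)^2)) < (L[1] + e$lengths_um[1]) / 2) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          Rm <- if (config$random_orientation) random_rotation() else diag(3)
          lacunae[[i]] <- ellipsoid(ctr, L, Rm)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("infeasible packing: placed only %d of %d non-overlapping lacunae",
                     length(lacunae), config$n_lacunae))
    }
  }

  canaliculi <- list()
  if (length(lacunae) > 0 && config$n_canaliculi > 0) {
    for (i in seq_along(lacunae)) {
      e <- lacunae[[i]]
      dirs <- if (config$tube_directions == "even") {
        fibonacci_directions(config$n_canaliculi)
      } else {
        m <- matrix(rnorm(3 * config$n_canaliculi), ncol = 3)
        m / sqrt(rowSums(m^2))
      }
      for (t in seq_len(config$n_canaliculi)) {
        u <- dirs[t, ]
        p0 <- ellipsoid_surface_point(e, u)
        canaliculi <- c(canaliculi,
                        grow_tube(p0, u, config$canaliculi_length_um,
                                  config$canaliculi_radius_um, i,
                                  branch_at = config$branch_at_um,
                                  branch_angle = config$branch_angle_deg * pi / 180,
                                  depth = 0, arc_done = 0))
      }
    }
  }

  structure(list(lacunae = lacunae,
                 canaliculi = canaliculi,
                 matrix_gray = config$matrix_gray,
                 pore_gray = config$pore_gray,
                 noise_sigma = config$noise_sigma,
                 salt_pepper_fraction = config$salt_pepper_fraction,
                 domain_um = config$domain_um,
                 config = config,
                 rng_seed = as.integer(seed)),
            class = "lcn_scene")
}

# Recursively grow one tube from p0 along u; returns a list of capsule
# segments {p0, p1, radius_um, lacuna, depth}.
grow_tube <- function(p0, u, total_len, radius, lacuna, branch_at, branch_angle,
                      depth, arc_done) {
  remaining <- total_len - arc_done
  if (remaining <= 0) return(list())
  pending <- if (is.null(branch_at)) numeric(0) else branch_at[branch_at > arc_done]
  next_branch <- if (length(pending)) min(pending) else Inf
  seg_len <- min(remaining, next_branch - arc_done)
  p1 <- p0 + u * seg_len
  seg <- list(list(p0 = p0, p1 = p1, radius_um = radius,
                   lacuna = lacuna, depth = depth))
  if (is.finite(next_branch) && next_branch - arc_done < remaining) {
    # bifurcate: two children, tilted +/- branch_angle around a random
    # axis perpendicular to u
    a <- rnorm(3)
    a <- a - sum(a * u) * u
    a <- a / sqrt(sum(a^2))
    for (s in c(-1, 1)) {
      v <- rotate_about(u, a, s * branch_angle)
      seg <- c(seg, grow_tube(p1, v, total_len, radius, lacuna, branch_at,
                              branch_angle, depth + 1, next_branch))
    }
  }
  seg
}

#' @export
print.lcn_scene <- function(x, ...) {
  cat(sprintf("<lcn_scene> %d lacunae, %d tube segments in %s um domain (seed %d)\n",
              length(x$lacunae), length(x$canaliculi),
              paste(signif(x$domain_um, 4), collapse = " x "), x$rng_seed))
  invisible(x)
}

#' Ground-truth number of canaliculi crossing a shell at distance r
#'
#' By construction every tube starts on its parent lacuna's surface and runs
#' radially outward, so at arc-length distance `r` the number of crossings is
#' the tube count doubled once per bifurcation passed before `r`. For
#' spherical lacunae the shell at distance `r` coincides with arc length `r`
#' along the tube, which is why count tests use spherical lacunae.
#'
#' @param scene an `lcn_scene`.
#' @param r_um distance from the lacunar surface (um).
#' @return integer vector, one expected count per lacuna.
#' @export
scene_ca_n <- function(scene, r_um) {
  cfg <- scene$config
  n_branch_passed <- if (is.null(cfg$branch_at_um)) 0 else sum(cfg$branch_at_um < r_um)
  reach <- cfg$canaliculi_length_um > r_um
  counts <- if (reach) cfg$n_canaliculi * 2^n_branch_passed else 0L
  rep.int(as.integer(counts), length(scene$lacunae))
}

# ---- rasterization -------------------------------------------------------

# Coverage of one ellipsoid on the voxel grid described by (dims, h_um,
# offset_um): updates cov (3D array) in place via pmax and returns it.
cover_ellipsoid <- function(cov, e, dims, h, offset) {
  semi_max <- e$lengths_um[1] / 2
  lo <- pmax(1L, floor((e$center_um - semi_max - offset) / h - 1) + 1L)
  hi <- pmin(dims, ceiling((e$center_um + semi_max - offset) / h + 1))
  if (any(lo > hi)) return(cov)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- offset[1] + (ii - 0.5) * h
  ys <- offset[2] + (jj - 0.5) * h
  zs <- offset[3] + (kk - 0.5) * h
  pts <- cbind(rep(xs, times = length(ys) * length(zs)),
               rep(rep(ys, each = length(xs)), times = length(zs)),
               rep(zs, each = length(xs) * length(ys)))
  q <- ellipsoid_quadform(e, pts)
  rho <- sqrt(q)
  rad <- sqrt(rowSums(sweep(pts, 2, e$center_um)^2))
  dist_approx <- rad * (1 - 1 / pmax(rho, 1e-12))   # signed, <0 inside
  band <- h * sqrt(3)                               # generous boundary band
  frac <- as.numeric(dist_approx < -band)           # fully inside
  bnd <- which(abs(dist_approx) <= band)
  if (length(bnd)) {
    off1 <- c(-1, 0, 1) * (h / 3)
    sub <- as.matrix(expand.grid(off1, off1, off1))
    acc <- numeric(length(bnd))
    for (s in seq_len(nrow(sub))) {
      qs <- ellipsoid_quadform(e, sweep(pts[bnd, , drop = FALSE], 2, -sub[s, ]))
      acc <- acc + (qs <= 1)
    }
    frac[bnd] <- acc / nrow(sub)
  }
  blk <- array(frac, dim = c(length(ii), length(jj), length(kk)))
  cov[ii, jj, kk] <- pmax(cov[ii, jj, kk], blk)
  cov
}

# Signed distance from points to a capsule (segment p0-p1 with radius).
capsule_sdist <- function(pts, p0, p1, radius) {
  v <- p1 - p0
  vv <- sum(v^2)
  d <- sweep(pts, 2, p0)
  t <- if (vv > 0) pmin(pmax((d %*% v) / vv, 0), 1) else 0
  dx <- d[, 1] - t * v[1]
  dy <- d[, 2] - t * v[2]
  dz <- d[, 3] - t * v[3]
  sqrt(dx^2 + dy^2 + dz^2) - radius
}

cover_capsule <- function(cov, seg, dims, h, offset) {
  pad <- seg$radius_um + 2 * h
  lo <- pmax(1L, floor((pmin(seg$p0, seg$p1) - pad - offset) / h) + 1L)
  hi <- pmin(dims, ceiling((pmax(seg$p0, seg$p1) + pad - offset) / h))
  if (any(lo > hi)) return(cov)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  xs <- offset[1] + (ii - 0.5) * h
  ys <- offset[2] + (jj - 0.5) * h
  zs <- offset[3] + (kk - 0.5) * h
  pts <- cbind(rep(xs, times = length(ys) * length(zs)),
               rep(rep(ys, each = length(xs)), times = length(zs)),
               rep(zs, each = length(xs) * length(ys)))
  sd <- capsule_sdist(pts, seg$p0, seg$p1, seg$radius_um)
  band <- h * 0.9                                    # > max subpoint offset
  frac <- as.numeric(sd < -band)
  bnd <- which(abs(sd) <= band)
  if (length(bnd)) {
    off1 <- c(-1, 0, 1) * (h / 3)
    sub <- as.matrix(expand.grid(off1, off1, off1))
    acc <- numeric(length(bnd))
    for (s in seq_len(nrow(sub))) {
      sds <- capsule_sdist(sweep(pts[bnd, , drop = FALSE], 2, -sub[s, ]),
                           seg$p0, seg$p1, seg$radius_um)
      acc <- acc + (sds <= 0)
    }
    frac[bnd] <- acc / nrow(sub)
  }
  blk <- array(frac, dim = c(length(ii), length(jj), length(kk)))
  cov[ii, jj, kk] <- pmax(cov[ii, jj, kk], blk)
  cov
}

# Voxel grid dims that fit the scene domain at a voxel size / offset.
default_raster_dims <- function(scene, voxel_size_nm, offset_um) {
  h <- voxel_size_nm / 1000
  pmax(1L, as.integer(floor((scene$domain_um - offset_um) / h + 1e-9)))
}

#' Rasterize a phantom scene into a gray-level volume
#'
#' Gray value is `pore_gray` inside any lacuna or tube and `matrix_gray` in
#' the matrix; boundary voxels get a partial-volume gray from the occupied
#' volume fraction estimated by 3^3 supersampling. Independent additive
#' Gaussian noise (and optional salt-and-pepper impulses) is applied last.
#' Deterministic for a fixed `noise_seed`.
#'
#' @param scene an [build_scene()] result.
#' @param voxel_size_nm voxel size (nm).
#' @param offset_um position of the raster corner within the scene (um).
#' @param dims grid dimensions; defaults to the largest grid fitting the
#'   domain.
#' @param noise_sigma noise level; defaults to the scene's.
#' @param noise_seed seed for the noise stream (defaults to the scene seed).
#' @return an [scalar_volume()] whose `origin_um` records `offset_um`.
#' @export
rasterize_scene <- function(scene, voxel_size_nm, offset_um = c(0, 0, 0),
                            dims = NULL, noise_sigma = scene$noise_sigma,
                            noise_seed = scene$rng_seed) {
  stopifnot(inherits(scene, "lcn_scene"))
  if (voxel_size_nm <= 0) stop("voxel size must be positive")
  h <- voxel_size_nm / 1000
  if (is.null(dims)) dims <- default_raster_dims(scene, voxel_size_nm, offset_um)
  dims <- as.integer(rep(dims, length.out = 3))
  if (any(offset_um < -1e-9) || any(offset_um + dims * h > scene$domain_um + 1e-9))
    stop("voxel grid exceeds the scene domain")
  cov <- array(0, dim = dims)
  for (e in scene$lacunae) cov <- cover_ellipsoid(cov, e, dims, h, offset_um)
  for (seg in scene$canaliculi) cov <- cover_capsule(cov, seg, dims, h, offset_um)
  g <- scene$matrix_gray + cov * (scene$pore_gray - scene$matrix_gray)
  if (noise_sigma > 0 || scene$salt_pepper_fraction > 0) {
    set.seed(noise_seed)
    if (noise_sigma > 0)
      g <- g + array(rnorm(length(g), 0, noise_sigma), dim = dims)
    if (scene$salt_pepper_fraction > 0) {
      n_imp <- round(scene$salt_pepper_fraction * length(g))
      if (n_imp > 0) {
        at <- sample.int(length(g), n_imp)
        half <- seq_len(n_imp) %% 2 == 0
        g[at[half]] <- scene$pore_gray
        g[at[!half]] <- scene$matrix_gray
      }
    }
  }
  scalar_volume(g, voxel_size_nm, origin_um = offset_um)
}

#' Noise-free ground-truth masks for a scene
#'
#' Rasterizes the scene's geometry with a centre-in-object test on the same
#' grid as [rasterize_scene()]: an integer label volume for the lacunae
#' (labels follow scene order) and a binary canaliculi mask disjoint from the
#' lacunae.
#'
#' @inheritParams rasterize_scene
#' @return list with `lacunae` (integer array), `canaliculi` (logical array),
#'   `voxel_size_nm`, `offset_um`.
#' @export
scene_ground_truth <- function(scene, voxel_size_nm, offset_um = c(0, 0, 0),
                               dims = NULL) {
  stopifnot(inherits(scene, "lcn_scene"))
  h <- voxel_size_nm / 1000
  if (is.null(dims)) dims <- default_raster_dims(scene, voxel_size_nm, offset_um)
  dims <- as.integer(rep(dims, length.out = 3))
  if (any(offset_um < -1e-9) || any(offset_um + dims * h > scene$domain_um + 1e-9))
    stop("voxel grid exceeds the scene domain")
  labels <- array(0L, dim = dims)
  for (i in seq_along(scene$lacunae)) {
    e <- scene$lacunae[[i]]
    semi_max <- e$lengths_um[1] / 2
    lo <- pmax(1L, floor((e$center_um - semi_max - offset_um) / h) + 1L)
    hi <- pmin(dims, ceiling((e$center_um + semi_max - offset_um) / h))
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    pts <- cbind(rep(offset_um[1] + (ii - 0.5) * h, times = length(jj) * length(kk)),
                 rep(rep(offset_um[2] + (jj - 0.5) * h, each = length(ii)),
                     times = length(kk)),
                 rep(offset_um[3] + (kk - 0.5) * h, each = length(ii) * length(jj)))
    inside <- ellipsoid_quadform(e, pts) <= 1
    blk <- labels[ii, jj, kk, drop = FALSE]
    blk[inside] <- i
    labels[ii, jj, kk] <- blk
  }
  can <- array(FALSE, dim = dims)
  for (seg in scene$canaliculi) {
    pad <- seg$radius_um + h
    lo <- pmax(1L, floor((pmin(seg$p0, seg$p1) - pad - offset_um) / h) + 1L)
    hi <- pmin(dims, ceiling((pmax(seg$p0, seg$p1) + pad - offset_um) / h))
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    pts <- cbind(rep(offset_um[1] + (ii - 0.5) * h, times = length(jj) * length(kk)),
                 rep(rep(offset_um[2] + (jj - 0.5) * h, each = length(ii)),
                     times = length(kk)),
                 rep(offset_um[3] + (kk - 0.5) * h, each = length(ii) * length(jj)))
    inside <- capsule_sdist(pts, seg$p0, seg$p1, seg$radius_um) <= 0
    blk <- can[ii, jj, kk, drop = FALSE]
    blk[inside] <- TRUE
    can[ii, jj, kk] <- blk
  }
  can[labels > 0] <- FALSE
  list(lacunae = labels, canaliculi = can,
       voxel_size_nm = voxel_size_nm, offset_um = offset_um)
}

#' Serialize a scene to JSON / read it back
#'
#' Scenes are continuous-domain ground truth, so a structured text file
#' round-trips them exactly (numbers are written at full precision).
#'
#' @param scene an `lcn_scene`.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_scene()` returns the `lcn_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "lcn_scene"))
  obj <- list(
    lacunae = lapply(scene$lacunae, function(e)
      list(center_um = e$center_um, lengths_um = e$lengths_um,
           rotation = as.numeric(e$rotation))),
    canaliculi = lapply(scene$canaliculi, function(s)
      list(p0 = s$p0, p1 = s$p1, radius_um = s$radius_um,
           lacuna = s$lacuna, depth = s$depth)),
    matrix_gray = scene$matrix_gray, pore_gray = scene$pore_gray,
    noise_sigma = scene$noise_sigma,
    salt_pepper_fraction = scene$salt_pepper_fraction,
    domain_um = scene$domain_um, rng_seed = scene$rng_seed,
    config = unclass(scene$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- obj$config
  cfg$branch_at_um <- if (is.null(cfg$branch_at_um)) NULL else
    as.numeric(cfg$branch_at_um)
  class(cfg) <- "lcn_phantom_config"
  structure(list(
    lacunae = lapply(obj$lacunae, function(e)
      ellipsoid(e$center_um, e$lengths_um, matrix(e$rotation, 3, 3))),
    canaliculi = lapply(obj$canaliculi, function(s)
      list(p0 = as.numeric(s$p0), p1 = as.numeric(s$p1),
           radius_um = s$radius_um, lacuna = as.integer(s$lacuna),
           depth = as.integer(s$depth))),
    matrix_gray = obj$matrix_gray, pore_gray = obj$pore_gray,
    noise_sigma = obj$noise_sigma,
    salt_pepper_fraction = obj$salt_pepper_fraction,
    domain_um = as.numeric(obj$domain_um),
    config = cfg,
    rng_seed = as.integer(obj$rng_seed)), class = "lcn_scene")
}

#' Co-located fine/coarse raster pair with a known translation
#'
#' Emulates the dual-resolution acquisition protocol: the same site scanned at
#' a fine and a coarse voxel size, where the fine volume covers a subregion of
#' the coarse one at a known integer offset on the coarse grid. The pair is
#' the input for phase-correlation registration.
#'
#' @param scene an `lcn_scene`.
#' @param fine_nm fine voxel size (nm), e.g. 30.
#' @param factor integer voxel-size ratio coarse/fine, e.g. 4 (30 -> 120 nm).
#' @param fine_dims dimensions of the fine grid (multiple of `factor`).
#' @param true_offset integer 3-vector: position of the fine volume's corner
#'   on the coarse grid, in coarse voxels.
#' @param noise_sigma noise level for both rasters.
#' @return list with `fine`, `coarse` ([scalar_volume()]) and `true_offset`.
#' @export
raster_pair <- function(scene, fine_nm, factor, fine_dims, true_offset,
                        noise_sigma = scene$noise_sigma) {
  coarse_nm <- fine_nm * factor
  hc <- coarse_nm / 1000
  true_offset <- as.integer(rep(true_offset, length.out = 3))
  fine_dims <- as.integer(rep(fine_dims, length.out = 3))
  if (any(fine_dims %% factor != 0))
    stop("fine_dims must be divisible by `factor`")
  coarse <- rasterize_scene(scene, coarse_nm, noise_sigma = noise_sigma,
                            noise_seed = scene$rng_seed + 1L)
  off_um <- true_offset * hc
  fine <- rasterize_scene(scene, fine_nm, offset_um = off_um, dims = fine_dims,
                          noise_sigma = noise_sigma,
                          noise_seed = scene$rng_seed + 2L)
  cdims <- dim(coarse$values)
  if (any(true_offset < 0) || any(true_offset + fine_dims / factor > cdims))
    stop("fine volume extends beyond the coarse grid")
  list(fine = fine, coarse = coarse, true_offset = true_offset)
}
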