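# FFT-based separable Gaussian smoothing with edge-replication padding.
gaussian_smooth_fft <- function(arr, sigma_vox) {
  d <- dim(arr)
  pad <- pmin(d, ceiling(3 * sigma_vox) + 1)
  big <- arr
  for (ax in 1:3) {
    dd <- dim(big)
    idx <- lapply(dd, seq_len)
    first <- rep(1L, pad[ax])
    last <- rep(dd[ax], pad[ax])
    idx[[ax]] <- c(first, seq_len(dd[ax]), last)
    big <- do.call(`[`, c(list(big), idx, list(drop = FALSE)))
  }
  dbig <- dim(big)
  tf <- function(n) {
    x <- c(0:(n %/% 2), -(((n + 1) %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_vox^2))
    Re(fft(k / sum(k)))            # symmetric kernel -> real transfer
  }
  A <- fft(big)
  A <- A * tf(dbig[1])
  A <- A * rep(tf(dbig[2]), each = dbig[1])
  A <- A * rep(tf(dbig[3]), each = dbig[1] * dbig[2])
  sm <- Re(fft(A, inverse = TRUE)) / length(A)
  sm <- array(sm, dim = dbig)
  sm[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3]),
     drop = FALSE]
}

# Hessian of a smoothed array by central differences (edge-replicated).
hessian3 <- function(f) {
  fx_p <- shift_edge(f, 1, 1); fx_m <- shift_edge(f, 1, -1)
  fy_p <- shift_edge(f, 2, 1); fy_m <- shift_edge(f, 2, -1)
  fz_p <- shift_edge(f, 3, 1); fz_m <- shift_edge(f, 3, -1)
  list(
    xx = fx_p - 2 * f + fx_m,
    yy = fy_p - 2 * f + fy_m,
    zz = fz_p - 2 * f + fz_m,
    xy = (shift_edge(fx_p, 2, 1) - shift_edge(fx_p, 2, -1) -
            shift_edge(fx_m, 2, 1) + shift_edge(fx_m, 2, -1)) / 4,
    xz = (shift_edge(fx_p, 3, 1) - shift_edge(fx_p, 3, -1) -
            shift_edge(fx_m, 3, 1) + shift_edge(fx_m, 3, -1)) / 4,
    yz = (shift_edge(fy_p, 3, 1) - shift_edge(fy_p, 3, -1) -
            shift_edge(fy_m, 3, 1) + shift_edge(fy_m, 3, -1)) / 4
  )
}

#' Multiscale Hessian vesselness (Frangi-form) for dark tubes
#'
#' Enhances 3D tube-like structures. At each Gaussian scale the volume is
#' smoothed, the Hessian eigenvalues `|l1| <= |l2| <= |l3|` are computed per
#' voxel (gamma-normalized by sigma^2), and the tube response combines a
#' plate/line discriminant `Ra = |l2|/|l3|`, a blobness term
#' `Rb = |l1|/sqrt(|l2 l3|)` and the structure strength
#' `S = sqrt(l1^2+l2^2+l3^2)`:
#' `v = (1-exp(-Ra^2/2a^2)) exp(-Rb^2/2b^2) (1-exp(-S^2/2c^2))`,
#' zeroed where the bright-tube sign condition (`l2 < 0` and `l3 < 0` after
#' inverting the dark-pore volume) fails. The output is the maximum over
#' scales, in [0, 1].
#'
#' @param vol an [scalar_volume()]; tubes darker than background by default.
#' @param scales_nm Gaussian scales (standard deviations) in nanometres;
#'   the response for an ideal tube peaks at a scale close to the tube
#'   radius. Every scale must be at least half a voxel.
#' @param alpha,beta sensitivity of the `Ra` and `Rb` terms (defaults 0.5).
#' @param c structure-strength sensitivity; `NULL` uses half the maximum
#'   strength at each scale (a standard data-driven choice).
#' @param dark_tubes if `TRUE` (default) the volume is inverted internally so
#'   dark channels become bright ridges.
#' @return object of class `lcn_vesselness`: `values` in [0,1],
#'   `scales_used`, `voxel_size_nm`.
#' @export
vesselness <- function(vol, scales_nm, alpha = 0.5, beta = 0.5, c = NULL,
                       dark_tubes = TRUE) {
  stopifnot(inherits(vol, "lcn_volume"))
  if (!length(scales_nm) || any(scales_nm <= 0)) stop("scales must be positive")
  if (any(scales_nm < vol$voxel_size_nm / 2))
    stop("scale smaller than half a voxel is unresolvable")
  I <- vol$values
  if (dark_tubes) I <- -I
  best <- array(0, dim = dim(I))
  for (s_nm in scales_nm) {
    s <- s_nm / vol$voxel_size_nm
    f <- gaussian_smooth_fft(I, s)
    H <- hessian3(f)
    g <- s^2                                  # gamma normalization
    ev <- eig_sym3(g * H$xx, g * H$yy, g * H$zz, g * H$xy, g * H$xz, g * H$yz)
    # order by absolute value: l1 smallest ... l3 largest (vectorized;
    # tie-breaks are deterministic and immaterial to the response)
    v1 <- as.numeric(ev$lo); v2 <- as.numeric(ev$mid); v3 <- as.numeric(ev$hi)
    a1 <- abs(v1); a2 <- abs(v2); a3 <- abs(v3)
    l3 <- ifelse(a1 >= a2 & a1 >= a3, v1, ifelse(a2 >= a3, v2, v3))
    l1 <- ifelse(a3 <= a1 & a3 <= a2, v3, ifelse(a2 <= a1, v2, v1))
    l2 <- v1 + v2 + v3 - l1 - l3
    ra <- abs(l2) / pmax(abs(l3), .Machine$double.eps)
    rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), .Machine$double.eps)
    st <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- if (is.null(c)) max(st) / 2 else c
    if (cc <= 0) cc <- .Machine$double.eps
    v <- (1 - exp(-ra^2 / (2 * alpha^2))) *
      exp(-rb^2 / (2 * beta^2)) *
      (1 - exp(-st^2 / (2 * cc^2)))
    v[l2 > 0 | l3 > 0] <- 0                   # bright-tube polarity test
    # numerical floor: homogeneous regions have no structure, not noise ridges
    v[st < 1e-8 * (1 + diff(range(I)))] <- 0
    best <- pmax(best, array(v, dim = dim(I)))
  }
  structure(list(values = best, scales_used = scales_nm,
                 voxel_size_nm = vol$voxel_size_nm),
            class = "lcn_vesselness")
}

#' @export
print.lcn_vesselness <- function(x, ...) {
  cat(sprintf("<lcn_vesselness> %s voxels, scales {%s} nm, max %.3f\n",
              paste(dim(x$values), collapse = " x "),
              paste(x$scales_used, collapse = ", "), max(x$values)))
  invisible(x)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the gray value `t` maximizing the sum of Shannon entropies of the
#' histogram partitions `x <= t` and `x > t`, on a 256-bin histogram spanning
#' the data range. Ties go to the lowest threshold.
#'
#' @param x numeric array or vector (e.g. a vesselness map), at least two
#'   distinct values.
#' @param n_bins number of histogram bins.
#' @return the threshold (a gray value strictly inside the data range).
#' @export
max_entropy_threshold <- function(x, n_bins = 256) {
  if (inherits(x, "lcn_vesselness") || inherits(x, "lcn_volume")) x <- x$values
  rng <- range(x)
  if (diff(rng) == 0) stop("constant input has no threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  Hc <- cumsum(-plogp)
  Hn <- Hc[n_bins]
  t_idx <- seq_len(n_bins - 1)
  Pb <- P[t_idx]
  valid <- Pb > 0 & Pb < 1
  crit <- rep(-Inf, n_bins - 1)
  crit[valid] <- log(Pb[valid]) + Hc[t_idx][valid] / Pb[valid] +
    log(1 - Pb[valid]) + (Hn - Hc[t_idx][valid]) / (1 - Pb[valid])
  best <- which.max(crit)                     # which.max takes the first tie
  edges[best + 1]                             # upper edge of the below-part
}

#' Variational region growing
#'
#' Refines an initial binary segmentation by locally minimizing the discrete
#' energy
#' `E(O) = a Sum_{x in O} (I(x)-mu_in)^2 + a Sum_{x not in O} (I(x)-mu_out)^2
#'  - b Sum_{x in O} V(x)`,
#' which combines a two-region gray-level data term with a shape prior from
#' the vesselness map `V`. Each sweep visits the region boundary (both sides,
#' 6-neighbourhood) and flips every voxel whose individual flip decreases `E`
#' at the current region means; the means are then re-estimated. Because the
#' data term is separable given the means, each sweep strictly decreases `E`,
#' so the energy trace is non-increasing and the process stops at a local
#' minimum (no flips) or `max_iter`. In the pipeline this fills gaps and
#' reconnects canaliculi broken by noise.
#'
#' @param vol an [scalar_volume()] (original gray levels).
#' @param vmap an [vesselness()] map on the same grid (or numeric array).
#' @param init logical 3D array, the initial region. An empty `init` is a
#'   documented degenerate case and is returned unchanged.
#' @param alpha_data,beta_shape non-negative energy weights.
#' @param max_iter maximum number of sweeps.
#' @return logical 3D array with attribute `energy` (one value per sweep).
#' @export
variational_region_growing <- function(vol, vmap, init, alpha_data = 1,
                                       beta_shape = 0.5, max_iter = 50) {
  stopifnot(inherits(vol, "lcn_volume"))
  V <- if (inherits(vmap, "lcn_vesselness")) vmap$values else vmap
  check_same_grid(vol$values, V)
  check_same_grid(vol$values, init)
  if (alpha_data < 0 || beta_shape < 0) stop("weights must be >= 0")
  I <- vol$values
  mask <- init
  if (!any(mask)) {
    attr(mask, "energy") <- numeric(0)
    return(mask)
  }
  energy <- numeric(0)
  for (it in seq_len(max_iter)) {
    n_in <- sum(mask)
    mu_in <- mean(I[mask])
    mu_out <- if (n_in < length(I)) mean(I[!mask]) else mu_in
    # boundary voxels: any 6-neighbour in the other phase
    nb_other <- array(FALSE, dim = dim(mask))
    for (ax in 1:3) for (by in c(-1, 1))
      nb_other <- nb_other | (shift_edge(mask, ax, by) != mask)
    cand <- which(nb_other)
    if (!length(cand)) break
    Ic <- I[cand]
    inn <- mask[cand]
    dE <- numeric(length(cand))
    # out -> in
    dE[!inn] <- alpha_data * ((Ic[!inn] - mu_in)^2 - (Ic[!inn] - mu_out)^2) -
      beta_shape * V[cand[!inn]]
    # in -> out
    dE[inn] <- alpha_data * ((Ic[inn] - mu_out)^2 - (Ic[inn] - mu_in)^2) +
      beta_shape * V[cand[inn]]
    flip <- dE < 0
    if (!any(flip)) {
      energy <- c(energy, vrg_energy(I, V, mask, alpha_data, beta_shape))
      break
    }
    mask[cand[flip]] <- !mask[cand[flip]]
    energy <- c(energy, vrg_energy(I, V, mask, alpha_data, beta_shape))
    if (!any(mask) || all(mask)) break
  }
  attr(mask, "energy") <- energy
  mask
}

# Energy of a region under the VRG functional, means re-estimated.
vrg_energy <- function(I, V, mask, alpha_data, beta_shape) {
  n_in <- sum(mask)
  mu_in <- if (n_in > 0) mean(I[mask]) else 0
  mu_out <- if (n_in < length(I)) mean(I[!mask]) else 0
  alpha_data * (sum((I[mask] - mu_in)^2) + sum((I[!mask] - mu_out)^2)) -
    beta_shape * sum(V[mask])
}

#' Remove small connected components
#'
#' Deletes 26-connected components with fewer than `min_voxels` voxels;
#' the final noise-removal step of the canalicular segmentation.
#'
#' @param mask logical 3D array.
#' @param min_voxels minimum component size kept (voxels, >= 0).
#' @return logical 3D array.
#' @export
remove_small_components <- function(mask, min_voxels) {
  stopifnot(is.array(mask), is.logical(mask))
  if (min_voxels < 0) stop("min_voxels must be >= 0")
  if (min_voxels == 0 || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 26)
  sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_labels"))
  small <- which(sizes < min_voxels)
  if (length(small)) mask[array(lab %in% small, dim = dim(mask))] <- FALSE
  mask
}

#' Segment canaliculi from a gray-level volume
#'
#' The canalicular stage of the pipeline: multiscale vesselness enhancement,
#' maximum-entropy thresholding of the vesselness map to initialize the
#' region, variational region growing on the original gray levels, exclusion
#' of voxels already labeled as lacunae (so lacunar and canalicular
#' porosities add), and removal of small residual components.
#'
#' @param vol an [scalar_volume()].
#' @param lacunae logical array of segmented lacunae (excluded from the
#'   canaliculi mask); `NULL` for none.
#' @param scales_nm vesselness scales; default spans the physiological
#'   canalicular radius range (100-250 nm), clipped to resolvable scales.
#' @param alpha,beta,c vesselness sensitivities, see [vesselness()].
#' @param alpha_data,beta_shape,max_iter region-growing controls, see
#'   [variational_region_growing()].
#' @param min_component_voxels final small-component cutoff.
#' @return list with `canaliculi` (logical array), `vesselness_map`,
#'   `threshold`, and the VRG `energy` trace.
#' @export
segment_canaliculi <- function(vol, lacunae = NULL,
                               scales_nm = NULL,
                               alpha = 0.5, beta = 0.5, c = NULL,
                               alpha_data = 1, beta_shape = 0.5,
                               max_iter = 20,
                               min_component_voxels = 5) {
  stopifnot(inherits(vol, "lcn_volume"))
  if (is.null(scales_nm)) {
    scales_nm <- unique(pmax(c(100, 150, 250), vol$voxel_size_nm / 2 + 1e-9))
  }
  vmap <- vesselness(vol, scales_nm, alpha = alpha, beta = beta, c = c)
  thr <- max_entropy_threshold(vmap$values)
  init <- vmap$values > thr
  if (!is.null(lacunae)) init[lacunae] <- FALSE
  grown <- variational_region_growing(vol, vmap, init, alpha_data = alpha_data,
                                      beta_shape = beta_shape,
                                      max_iter = max_iter)
  energy <- attr(grown, "energy")
  if (!is.null(lacunae)) grown[lacunae] <- FALSE
  out <- remove_small_components(grown, min_component_voxels)
  attr(out, "energy") <- NULL
  list(canaliculi = out, vesselness_map = vmap, threshold = thr,
       energy = energy)
}
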