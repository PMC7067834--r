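make_profile_volume <- function(kind, radius_nm = 150, voxel_nm = 100, n = 41) {
  mid <- (n + 1) / 2
  xs <- (seq_len(n) - mid) * voxel_nm
  g <- expand.grid(xs, xs, xs)
  inside <- switch(kind,
                   cylinder = g[, 1]^2 + g[, 2]^2 <= radius_nm^2,
                   plate = abs(g[, 1]) <= radius_nm,
                   sphere = rowSums(g^2) <= radius_nm^2)
  scalar_volume(array(1 - as.numeric(inside), c(n, n, n)), voxel_nm)
}

test_that("vesselness singles out tubes among plate, sphere and constant", {
  mid <- 21
  vc <- vesselness(make_profile_volume("cylinder"), 150)$values[mid, mid, mid]
  vp <- vesselness(make_profile_volume("plate"), 150)$values[mid, mid, mid]
  vs <- vesselness(make_profile_volume("sphere"), 150)$values[mid, mid, mid]
  expect_gt(vc, vp)         # plates suppressed by the Ra term
  expect_gt(vc, vs)         # blobs suppressed by the Rb term
  v0 <- vesselness(scalar_volume(array(0.5, c(12, 12, 12)), 100), 150)
  expect_true(all(v0$values == 0))
  expect_true(all(vc >= 0 & vc <= 1))
  expect_error(vesselness(make_profile_volume("cylinder"), 40), "unresolvable")
})

test_that("the vesselness argmax scale tracks the tube radius", {
  vol <- make_profile_volume("cylinder", radius_nm = 150, voxel_nm = 50, n = 61)
  scales <- c(50, 100, 150, 200, 250)
  resp <- vapply(scales, function(s)
    vesselness(vol, s, c = 0.25)$values[31, 31, 31], numeric(1))
  best <- scales[which.max(resp)]
  expect_lte(abs(best - 150), 50)   # within one grid step of the radius
})

test_that("maximum-entropy threshold splits two-level data and shifts with it", {
  x <- c(rep(50, 500), rep(200, 500))
  t1 <- max_entropy_threshold(x)
  expect_gt(t1, 50)
  expect_lt(t1, 200)
  t2 <- max_entropy_threshold(x + 30)
  bin <- diff(range(x)) / 256
  expect_equal(t2 - t1, 30, tolerance = bin + 1e-9)
  expect_error(max_entropy_threshold(rep(1, 100)), "constant")
})

test_that("region growing is a fixed point on noise-free two-level data", {
  n <- c(21, 11, 11)
  tube <- array(FALSE, n); tube[, 6, 6] <- TRUE
  a <- array(1, n); a[tube] <- 0
  vol <- scalar_volume(a, 100)
  vm <- vesselness(vol, 100)
  out <- variational_region_growing(vol, vm, tube, 1, 0, max_iter = 30)
  expect_equal(as.vector(out), as.vector(tube))
})

test_that("region growing fills an intermediate-gray gap and lowers energy", {
  n <- c(21, 11, 11)
  tube <- array(FALSE, n); tube[, 6, 6] <- TRUE
  a <- array(1, n); a[tube] <- 0
  a[10:11, 6, 6] <- 0.55
  vol <- scalar_volume(a, 100)
  vm <- vesselness(vol, 100)
  init <- tube; init[10:11, 6, 6] <- FALSE
  out <- variational_region_growing(vol, vm, init, 1, 0.5, max_iter = 30)
  expect_true(out[10, 6, 6] && out[11, 6, 6])
  expect_equal(sum(out), sum(tube))          # gap filled, nothing else added
  energy <- attr(out, "energy")
  expect_true(all(diff(energy) <= 1e-9))     # non-increasing per sweep
})

test_that("region growing leaves an empty initialization empty", {
  set.seed(3)
  vol <- scalar_volume(array(rnorm(10^3, 1, 0.1), c(10, 10, 10)), 100)
  vm <- vesselness(vol, 100)
  out <- variational_region_growing(vol, vm, array(FALSE, c(10, 10, 10)),
                                    1, 0.1, max_iter = 10)
  expect_false(any(out))
})

test_that("small-component removal deletes only undersized components", {
  m <- array(FALSE, c(20, 20, 20))
  m[2:6, 2:3, 2:6] <- TRUE      # 50 voxels
  m[15, 15, 10:14] <- TRUE      # 5 voxels
  out <- remove_small_components(m, 10)
  expect_true(all(out[2:6, 2:3, 2:6]))
  expect_false(any(out[15, 15, 10:14]))
  expect_identical(remove_small_components(m, 0), m)
})

test_that("the canalicular stage recovers phantom tubes with Dice >= 0.8", {
  sc <- make_tissue_scene(seed = 11, n_lacunae = 1, n_canaliculi = 10,
                          domain_um = 7.68, noise_sigma = 0.05)
  vol <- rasterize_scene(sc, 60)   # 128^3, tube radius 2.5 voxels
  seg <- segment_lacunae(vol, t_seed = 0.25, t_keep = 0.5,
                         max_lacuna_volume_um3 = 1e5,
                         min_lacuna_volume_um3 = 1)
  can <- segment_canaliculi(vol, lacunae = seg$labels > 0,
                            scales_nm = c(100, 150),
                            min_component_voxels = 27)
  gt <- scene_ground_truth(sc, 60)
  expect_gte(dice_overlap(can$canaliculi, gt$canaliculi), 0.8)
  # energy trace of the embedded VRG is non-increasing
  expect_true(all(diff(can$energy) <= 1e-9))
})
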