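test_that("median filter matches a brute-force neighbourhood oracle", {
  set.seed(1)
  v <- scalar_volume(array(runif(6^3), c(6, 6, 6)), 100)
  mf <- median_filter3(v, 1)
  # interior voxel: median of the 27-neighbourhood
  expect_equal(mf$values[3, 4, 3], median(v$values[2:4, 3:5, 2:4]))
  # edge voxel with mirrored neighbours
  mirror <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  vals <- apply(nb, 1, function(o)
    v$values[mirror(1 + o[1], 6), mirror(2 + o[2], 6), mirror(6 + o[3], 6)])
  expect_equal(mf$values[1, 2, 6], median(vals))
})

test_that("median filter keeps constants, removes impulses, preserves interiors", {
  v <- scalar_volume(array(0.7, c(8, 8, 8)), 100)
  expect_equal(median_filter3(v, 1)$values, v$values)
  # single dark impulse in a bright field vanishes
  a <- array(1, c(9, 9, 9)); a[5, 5, 5] <- 0
  out <- median_filter3(scalar_volume(a, 100), 1)
  expect_equal(out$values[5, 5, 5], 1)
  # a dark blob much larger than the kernel keeps its interior
  b <- array(1, c(15, 15, 15)); b[4:12, 4:12, 4:12] <- 0.1
  outb <- median_filter3(scalar_volume(b, 100), 1)
  expect_equal(outb$values[8, 8, 8], 0.1)
  expect_error(median_filter3(v, 10), "radius")
})

test_that("hysteresis keeps seeded blobs and drops unseeded ambiguous ones", {
  a <- array(1, c(12, 12, 12))
  a[3:5, 3:5, 3:5] <- 0.4       # blob in the ambiguous band ...
  a[4, 4, 4] <- 0.1             # ... with a dark core seed
  a[9:10, 9:10, 9:10] <- 0.4    # isolated ambiguous blob, no seed
  v <- scalar_volume(a, 100)
  m <- hysteresis_segment(v, 0.2, 0.5)
  expect_true(all(m[3:5, 3:5, 3:5]))
  expect_false(any(m[9:10, 9:10, 9:10]))
  expect_equal(sum(m), 27)
  # all values above t_keep -> empty mask
  expect_false(any(hysteresis_segment(scalar_volume(array(1, c(4, 4, 4)), 100),
                                      0.2, 0.5)))
  expect_error(hysteresis_segment(v, 0.6, 0.5), "t_seed")
})

test_that("hysteresis reduces to plain thresholding and is monotone in t_keep", {
  set.seed(2)
  v <- scalar_volume(array(runif(10^3), c(10, 10, 10)), 100)
  expect_identical(hysteresis_segment(v, 0.3, 0.3),
                   array(v$values <= 0.3, dim = c(10, 10, 10)))
  for (tk in c(0.35, 0.45, 0.6)) {
    m1 <- hysteresis_segment(v, 0.2, tk)
    m2 <- hysteresis_segment(v, 0.2, tk + 0.1)
    expect_true(all(m2[m1]))   # raising t_keep never removes a voxel
  }
})

test_that("size splitting sends only oversize components to canals", {
  m <- array(FALSE, c(30, 30, 30))
  m[2:25, 2:25, 2:6] <- TRUE            # ~ 2880 voxels
  m[15:17, 15:17, 20:22] <- TRUE        # 27 voxels
  h <- 1000                              # 1 um voxels
  sp <- split_by_size(m, h, max_volume_um3 = 500)
  expect_true(all(sp$canals[2:25, 2:25, 2:6]))
  expect_true(all(sp$lacunae[15:17, 15:17, 20:22]))
  expect_false(any(sp$lacunae & sp$canals))
  # nothing oversize -> identity
  sp2 <- split_by_size(m, h, max_volume_um3 = 1e6)
  expect_identical(sp2$lacunae, m)
  expect_false(any(sp2$canals))
})

test_that("labeling orders components by decreasing volume with a floor", {
  m <- array(FALSE, c(20, 20, 20))
  m[2:4, 2:4, 2:4] <- TRUE              # 27 voxels, second largest
  m[10:15, 10:15, 10:15] <- TRUE        # 216 voxels, largest
  m[18, 18, 18] <- TRUE                 # 1 voxel
  lab <- label_lacunae(m, 1000, min_volume_um3 = 2)
  expect_equal(attr(lab, "n_labels"), 2L)
  expect_equal(unique(as.integer(lab[10:15, 10:15, 10:15])), 1L)
  expect_equal(unique(as.integer(lab[2:4, 2:4, 2:4])), 2L)
  expect_equal(lab[18, 18, 18], 0L)
  empty <- label_lacunae(array(FALSE, c(4, 4, 4)), 1000)
  expect_true(all(empty == 0L))
  expect_equal(attr(empty, "n_labels"), 0L)
})

test_that("noise-free phantom lacunae are recovered to a one-voxel band", {
  sc <- make_tissue_scene(seed = 21, n_lacunae = 5, n_canaliculi = 0,
                          domain_um = 19.2, noise_sigma = 0)
  vol <- rasterize_scene(sc, 150)   # 128^3
  seg <- segment_lacunae(vol, t_seed = 0.25, t_keep = 0.75,
                         max_lacuna_volume_um3 = 1e5,
                         min_lacuna_volume_um3 = 1)
  expect_equal(attr(seg$labels, "n_labels"), 5L)
  gt <- scene_ground_truth(sc, 150)
  # any disagreement lies within one voxel of the ground-truth boundary
  diff_vox <- (seg$labels > 0) != (gt$lacunae > 0)
  if (any(diff_vox)) {
    dist_gt <- lcnmorph:::edt_voxels(gt$lacunae > 0)
    dist_bg <- lcnmorph:::edt_voxels(gt$lacunae == 0)
    band <- pmin(dist_gt, dist_bg) <= 1
    expect_true(all(band[diff_vox]))
  }
})
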