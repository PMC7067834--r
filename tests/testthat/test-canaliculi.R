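test_that("the default ramification grid holds the seven distances", {
  expect_equal(default_r_grid(), c(1.2, 3.0, 4.8, 6.6, 8.4, 10.2, 12.0))
})

test_that("analytic shells hug the dilated ellipsoid at the right radius", {
  e <- ellipsoid(c(17, 17, 17), c(10, 10, 10))
  h <- 240
  # r = 0: shell voxels sit on the unit level set of the fitted ellipsoid
  sh0 <- dilated_shell(e, 0, c(142, 142, 142), h)
  idx <- which(sh0, arr.ind = TRUE)
  d0 <- sqrt(rowSums(sweep((idx - 0.5) * h / 1000, 2, e$center_um)^2))
  expect_true(all(abs(d0 - 5) <= h / 1000 * 1.5))
  # r = 2: radii concentrate at L/2 + 2 = 7 um
  sh2 <- dilated_shell(e, 2, c(142, 142, 142), h)
  idx2 <- which(sh2, arr.ind = TRUE)
  d2 <- sqrt(rowSums(sweep((idx2 - 0.5) * h / 1000, 2, e$center_um)^2))
  expect_true(all(abs(d2 - 7) <= h / 1000 * 1.5))
  # shell volume grows monotonically with r
  vols <- vapply(c(0, 1, 2, 3, 4), function(r)
    sum(dilated_shell(e, r, c(142, 142, 142), h)), numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_warning(dilated_shell(e, 40, c(142, 142, 142), h), "outside")
})

test_that("straight radial tubes are counted exactly at every distance", {
  sc <- make_counting_scene(12)
  gt <- scene_ground_truth(sc, 240)
  ef <- fit_ellipsoid(gt$lacunae == 1, 240)
  for (r in default_r_grid()) {
    expect_identical(count_canaliculi(gt$canaliculi, ef, r, 240), 12L)
  }
  # no canaliculi -> zero at every r
  none <- array(FALSE, dim = dim(gt$canaliculi))
  expect_identical(count_canaliculi(none, ef, 3, 240), 0L)
})

test_that("bifurcating tubes double the count past the branch distance", {
  sc <- make_counting_scene(10, branch_at_um = 6)
  gt <- scene_ground_truth(sc, 240)
  ef <- fit_ellipsoid(gt$lacunae == 1, 240)
  for (r in c(1.2, 3.0, 4.8))
    expect_identical(count_canaliculi(gt$canaliculi, ef, r, 240), 10L)
  for (r in c(8.4, 10.2, 12.0))
    expect_identical(count_canaliculi(gt$canaliculi, ef, r, 240), 20L)
})

test_that("analytic-shell counts equal morphological-dilation counts", {
  # the prior method this replaces: dilate the segmented lacuna by r with a
  # Euclidean distance transform and count canals crossing that shell
  sc <- make_counting_scene(9, radius_um = 0.3, length_um = 7,
                            domain_um = 22, seed = 13)
  h <- 240
  gt <- scene_ground_truth(sc, h)      # 91^3 grid
  ef <- fit_ellipsoid(gt$lacunae == 1, h)
  dist_vox <- lcnmorph:::edt_voxels(gt$lacunae == 1)
  for (r in c(1.2, 3.0, 4.8)) {
    analytic <- count_canaliculi(gt$canaliculi, ef, r, h)
    r_vox <- r / (h / 1000)
    shell <- dist_vox > r_vox - 0.5 & dist_vox <= r_vox + 0.5
    inter <- gt$canaliculi & shell
    lab <- lcnmorph:::label_components(inter, 26)
    expect_identical(analytic, as.integer(attr(lab, "n_labels")))
  }
})

test_that("canalicular metrics respect additivity and analytic tube volume", {
  sc <- make_counting_scene(12, radius_um = 0.3, length_um = 7,
                            domain_um = 22, seed = 13)
  h <- 120
  gt <- scene_ground_truth(sc, h)
  lab <- gt$lacunae
  part <- voronoi_partition(lab, h)
  ells <- fit_lacunae(lab, h)
  bv <- bone_volume(dim(lab), h)
  cm <- canal_metrics(gt$canaliculi, lab, part, ells, bv, h,
                      r_grid_um = c(1.2, 3.0))
  s <- cm$summary
  # LCN additivity is exact by construction
  lcm <- lacuna_metrics(lab, part, ells, bv, h)
  expect_equal(s[["LCN.TV"]], s[["Ca.TV"]] + lcm$summary[["Lc.TV"]])
  expect_equal(s[["LCN.TV/BV"]] - lcm$summary[["Lc.TV/BV"]], s[["Ca.TV/BV"]])
  # total canal volume within 10% of the analytic capsule volume
  # (12 cylinders of radius 0.3 and length 7, caps counted once)
  analytic_mm3 <- 12 * (pi * 0.3^2 * 7 + 2 / 3 * pi * 0.3^3) * 1e-9
  expect_equal(s[["Ca.TV"]], analytic_mm3, tolerance = 0.1)
  # empty canals: zero totals and ratios, LCN reduces to lacunae
  cm0 <- canal_metrics(array(FALSE, dim = dim(lab)), lab, part, ells, bv, h,
                       r_grid_um = c(1.2))
  expect_equal(cm0$summary[["Ca.TV"]], 0)
  expect_equal(cm0$summary[["LCN.TV"]], lcm$summary[["Lc.TV"]])
  expect_equal(cm0$summary[["Ca.V/Lc.V"]], 0)
  expect_equal(cm0$ca_n[["Ca.N"]], 0)
  expect_error(canal_metrics(gt$canaliculi, array(0L, dim = dim(lab)),
                             part, ells, bv, h), "zero lacunae")
})

test_that("Ca.N(r) is flat without branching and non-decreasing with it", {
  sc <- make_counting_scene(8, branch_at_um = 5, length_um = 12,
                            domain_um = 30, seed = 17)
  gt <- scene_ground_truth(sc, 240)
  ef <- fit_ellipsoid(gt$lacunae == 1, 240)
  counts <- vapply(c(1.2, 3.0, 7.5, 9.0), function(r)
    count_canaliculi(gt$canaliculi, ef, r, 240), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[1], 8L)
  expect_identical(counts[4], 16L)
})
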