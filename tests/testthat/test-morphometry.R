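test_that("bone volume subtracts Haversian canals from the VOI", {
  expect_equal(bone_volume(c(100, 100, 100), 1000), 1e-3)
  canals <- array(FALSE, c(10, 10, 10)); canals[, , 1] <- TRUE  # 10% of voxels
  expect_equal(bone_volume(c(10, 10, 10), 1000, canals),
               0.9 * bone_volume(c(10, 10, 10), 1000))
  # a 512^3 grid at 120 nm holds (61.44 um)^3 ~ 2.32e-4 mm^3
  expect_equal(bone_volume(c(512, 512, 512), 120), 61.44^3 * 1e-9)
})

test_that("object Voronoi matches brute-force nearest-object assignment", {
  lab <- array(0L, c(32, 32, 32))
  lab[8, 16, 16] <- 1L
  lab[25, 17, 15] <- 2L
  vp <- voronoi_partition(lab, 100)
  idx <- which(array(TRUE, c(32, 32, 32)), arr.ind = TRUE)
  d1 <- sqrt(rowSums(sweep(idx, 2, c(8, 16, 16))^2))
  d2 <- sqrt(rowSums(sweep(idx, 2, c(25, 17, 15))^2))
  oracle <- array(ifelse(d1 <= d2, 1L, 2L), c(32, 32, 32))  # tie -> lowest
  expect_identical(vp$cells, oracle)
  expect_equal(sum(vp$cell_volumes_um3), 32^3 * voxel_volume_um3(100))
  # distance is to the object, not the centroid: an extended lacuna wins
  # voxels nearer its far end
  lab2 <- array(0L, c(24, 8, 8))
  lab2[2:12, 4, 4] <- 1L          # rod
  lab2[20, 4, 4] <- 2L            # point
  vp2 <- voronoi_partition(lab2, 100)
  expect_equal(vp2$cells[14, 4, 4], 1L)  # 2 voxels from rod end, 6 from point
  # single lacuna -> one cell covering the domain
  lab3 <- array(0L, c(8, 8, 8)); lab3[4, 4, 4] <- 1L
  expect_true(all(voronoi_partition(lab3, 100)$cells == 1L))
  expect_error(voronoi_partition(array(0L, c(4, 4, 4)), 100), "label")
})

test_that("moment fit recovers sphere and ellipsoid dimensions within 2%", {
  ball <- digitize_ball(5, 120)
  e <- fit_ellipsoid(ball, 120)
  expect_equal(e$lengths_um, c(10, 10, 10), tolerance = 0.02)
  ell <- digitized_ellipsoid_fit(ellipsoid(c(0, 0, 0), c(20, 10, 5)), 120)
  expect_equal(ell$lengths_um, c(20, 10, 5), tolerance = 0.02)
  expect_error(fit_ellipsoid(array(FALSE, c(3, 3, 3))), "voxel")
  # coplanar voxels are degenerate
  flat <- array(FALSE, c(8, 8, 8)); flat[2:6, 2:6, 4] <- TRUE
  expect_error(fit_ellipsoid(flat, 120), "rank")
})

test_that("moment fit is invariant under rotation of the same ellipsoid", {
  set.seed(8)
  base <- c(18, 9, 4.5)
  for (i in 1:3) {
    e <- ellipsoid(c(0, 0, 0), base, lcnmorph:::random_rotation())
    f <- digitized_ellipsoid_fit(e, 60)
    expect_equal(f$lengths_um, base, tolerance = 0.005)
    # recovered major axis within 5 degrees of truth
    ang <- acos(min(1, abs(sum(f$rotation[, 1] * e$rotation[, 1])))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("Crofton surface area matches closed forms and scaling", {
  ball <- digitize_ball(5, 120)
  expect_equal(surface_area(ball, 120), 4 * pi * 25, tolerance = 0.03)
  # doubling every axis quadruples the surface
  ball2 <- digitize_ball(10, 240)    # same grid, double physical scale
  expect_equal(surface_area(ball2, 240) / surface_area(ball, 120), 4,
               tolerance = 1e-6)
  cyl <- digitize_cylinder(1.5, 30, 120)
  expect_equal(surface_area(cyl, 120),
               2 * pi * 1.5 * 30 + 2 * pi * 1.5^2, tolerance = 0.05)
  expect_error(surface_area(array(FALSE, c(3, 3, 3)), 120), "empty")
  # analytic ellipsoid route agrees with the voxel route on the ball
  expect_equal(surface_area(ellipsoid(c(0, 0, 0), c(10, 10, 10))),
               4 * pi * 25, tolerance = 1e-6)
})

test_that("SMI classifies reference solids as sphere, rod and plate", {
  expect_equal(smi(digitize_ball(2.5, 120), 120), 4, tolerance = 0.3)
  expect_equal(smi(digitize_cylinder(1.8, 30, 120), 120), 3, tolerance = 0.3)
  expect_equal(smi(digitize_plate(30, 0.36, 120), 120), 0, tolerance = 0.3)
})

test_that("lacunar metrics aggregate counts, porosities and shapes exactly", {
  lab <- array(0L, c(40, 40, 40))
  lab[4:9, 4:9, 4:9] <- 1L               # 216 voxels
  lab[25:30, 25:30, 25:30] <- 2L         # 216 voxels
  h <- 500
  part <- voronoi_partition(lab, h)
  ells <- fit_lacunae(lab, h)
  bv <- bone_volume(c(40, 40, 40), h)
  m <- lacuna_metrics(lab, part, ells, bv, h)
  s <- m$summary
  expect_equal(s[["Lc.N"]], 2L)
  expect_equal(s[["Lc.N/BV"]], 2 / bv)
  expect_equal(s[["Lc.TV"]], 432 * voxel_volume_um3(h) * 1e-9)
  # porosity identity to machine precision
  expect_equal(s[["Lc.TV/BV"]], 100 * s[["Lc.TV"]] / s[["BV"]])
  # identical cubes: per-lacuna values equal the mean
  expect_equal(m$per_lacuna[["Lc.V"]], rep(s[["Lc.V"]], 2))
  expect_true(s[["Lc.L1"]] >= s[["Lc.L2"]] && s[["Lc.L2"]] >= s[["Lc.L3"]])
  # zero-lacuna table flags undefined averages
  m0 <- lacuna_metrics(array(0L, c(5, 5, 5)), NULL, list(), bv, h)
  expect_equal(m0$summary[["Lc.N"]], 0L)
  expect_true(is.na(m0$summary[["Lc.V"]]))
})
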