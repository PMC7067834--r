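test_that("scene generation is deterministic and honours its invariants", {
  cfg <- phantom_config(domain_um = c(40, 40, 40), n_lacunae = 3,
                        n_canaliculi = 6, canaliculi_length_um = 5,
                        noise_sigma = 0.05)
  s1 <- build_scene(cfg, seed = 4)
  s2 <- build_scene(cfg, seed = 4)
  expect_identical(s1, s2)
  v1 <- rasterize_scene(s1, 400)
  v2 <- rasterize_scene(s2, 400)
  expect_identical(v1$values, v2$values)

  # pores darker than matrix
  expect_lt(s1$pore_gray, s1$matrix_gray)
  # every tube's first vertex lies on its parent lacuna's surface
  for (seg in s1$canaliculi[seq_len(10)]) {
    if (seg$depth > 0) next
    e <- s1$lacunae[[seg$lacuna]]
    q <- lcnmorph:::ellipsoid_quadform(e, matrix(seg$p0, 1, 3))
    expect_equal(as.numeric(q), 1, tolerance = 1e-8)
    expect_gt(seg$radius_um, 0)
  }
  # lacunae pairwise non-overlapping (bounding-sphere criterion)
  for (i in seq_along(s1$lacunae)) for (j in seq_len(i - 1)) {
    ei <- s1$lacunae[[i]]; ej <- s1$lacunae[[j]]
    expect_gte(sqrt(sum((ei$center_um - ej$center_um)^2)),
               (ei$lengths_um[1] + ej$lengths_um[1]) / 2)
  }
})

test_that("an empty scene rasterizes to constant matrix gray", {
  cfg <- phantom_config(domain_um = c(5, 5, 5), n_lacunae = 0,
                        noise_sigma = 0)
  sc <- build_scene(cfg, seed = 1)
  expect_length(sc$lacunae, 0)
  expect_length(sc$canaliculi, 0)
  v <- rasterize_scene(sc, 250)
  expect_true(all(v$values == sc$matrix_gray))
  gt <- scene_ground_truth(sc, 250)
  expect_true(all(gt$lacunae == 0L))
  expect_false(any(gt$canaliculi))
})

test_that("infeasible packing fails naming the achieved count", {
  cfg <- phantom_config(domain_um = c(20, 20, 20), n_lacunae = 40,
                        lacuna_axes_um = c(17.2, 9.4, 4.8),
                        n_canaliculi = 0, max_attempts = 30)
  expect_error(build_scene(cfg, seed = 1), "infeasible packing")
})

test_that("rasterized sphere volume matches the analytic value within 1%", {
  cfg <- phantom_config(domain_um = c(15, 15, 15), n_lacunae = 0,
                        n_canaliculi = 0, noise_sigma = 0)
  sc <- build_scene(cfg, seed = 1)
  sc$lacunae <- list(ellipsoid(c(7.5, 7.5, 7.5), c(10, 10, 10)))
  v <- rasterize_scene(sc, 100)
  pore <- sum(v$values < 0.5) * voxel_volume_um3(100)
  expect_equal(pore, pi / 6 * 1000, tolerance = 0.01)
})

test_that("rasterized pore volume converges monotonically with voxel size", {
  cfg <- phantom_config(domain_um = c(12, 12, 12), n_lacunae = 0,
                        n_canaliculi = 0, noise_sigma = 0)
  sc <- build_scene(cfg, seed = 1)
  sc$lacunae <- list(ellipsoid(c(6, 6, 6), c(8, 8, 8)))
  analytic <- 4 / 3 * pi * 4^3
  errs <- vapply(c(400, 200, 100), function(h_nm) {
    v <- rasterize_scene(sc, h_nm)
    abs(sum(v$values < 0.5) * voxel_volume_um3(h_nm) - analytic) / analytic
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.001)
})

test_that("sub-voxel tubes lose pore volume at the coarse raster", {
  # 0.3 um diameter tube: below the coarse voxel size, so identical
  # thresholding keeps less pore volume at 120 nm than at 30 nm
  cfg <- phantom_config(domain_um = c(7.68, 7.68, 7.68), n_lacunae = 0,
                        n_canaliculi = 0, noise_sigma = 0)
  sc <- build_scene(cfg, seed = 1)
  sc$canaliculi <- list(list(p0 = c(1, 3.84, 3.84), p1 = c(6.7, 3.84, 3.84),
                             radius_um = 0.15, lacuna = 1L, depth = 0L))
  vol_at <- function(h_nm) {
    v <- rasterize_scene(sc, h_nm)
    sum(v$values < 0.5) * voxel_volume_um3(h_nm)
  }
  expect_lt(vol_at(120), vol_at(30))
})

test_that("default configuration emulates 4:2:1 lacunar anisotropy", {
  sc <- build_scene(phantom_config(n_canaliculi = 0), seed = 2)
  L <- t(vapply(sc$lacunae, function(e) e$lengths_um, numeric(3)))
  expect_equal(mean(L[, 1] / L[, 2]), 2, tolerance = 0.2)
  expect_equal(mean(L[, 2] / L[, 3]), 2, tolerance = 0.2)
})

test_that("ground truth labels follow scene order and match the raster", {
  cfg <- phantom_config(domain_um = c(16, 16, 16), n_lacunae = 2,
                        lacuna_axes_um = c(5, 3, 2),
                        lacuna_axes_sd_um = c(0.1, 0.1, 0.1),
                        n_canaliculi = 4, canaliculi_length_um = 3,
                        noise_sigma = 0)
  sc <- build_scene(cfg, seed = 6)
  gt <- scene_ground_truth(sc, 160)
  expect_setequal(unique(as.integer(gt$lacunae[gt$lacunae > 0])), c(1L, 2L))
  # masks disjoint
  expect_false(any(gt$canaliculi & gt$lacunae > 0))
  # noise-free raster agrees with ground truth except in the partial-volume
  # boundary band (gray strictly between pore and matrix)
  v <- rasterize_scene(sc, 160, noise_sigma = 0)
  pore_gt <- gt$lacunae > 0 | gt$canaliculi
  pore_rast <- v$values < 0.5
  disagree <- which(pore_gt != pore_rast)
  expect_true(all(v$values[disagree] > sc$pore_gray &
                    v$values[disagree] < sc$matrix_gray))
})

test_that("scene records exact tube-count ground truth", {
  sc <- make_counting_scene(12)
  expect_identical(scene_ca_n(sc, 3), 12L)
  sc2 <- make_counting_scene(10, branch_at_um = 6)
  expect_identical(scene_ca_n(sc2, 3), 10L)
  expect_identical(scene_ca_n(sc2, 9), 20L)
})

test_that("scenes survive a JSON round trip and rasterize identically", {
  cfg <- phantom_config(domain_um = c(16, 16, 16), n_lacunae = 2,
                        lacuna_axes_um = c(5, 3, 2),
                        lacuna_axes_sd_um = c(0.1, 0.1, 0.1),
                        n_canaliculi = 4, canaliculi_length_um = 3,
                        noise_sigma = 0.05)
  sc <- build_scene(cfg, seed = 6)
  p <- file.path(tempdir(), "scene.json")
  write_scene(sc, p)
  sc2 <- read_scene(p)
  expect_equal(sc2$lacunae, sc$lacunae)
  expect_equal(length(sc2$canaliculi), length(sc$canaliculi))
  expect_identical(rasterize_scene(sc2, 320)$values,
                   rasterize_scene(sc, 320)$values)
})

test_that("raster grids larger than the scene domain are rejected", {
  cfg <- phantom_config(domain_um = c(5, 5, 5), n_lacunae = 0, noise_sigma = 0)
  sc <- build_scene(cfg, seed = 1)
  expect_error(rasterize_scene(sc, 250, dims = c(30, 30, 30)), "domain")
})
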