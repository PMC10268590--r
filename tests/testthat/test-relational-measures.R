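test_that("the distance field is exact on aligned and anisotropic cases", {
  m <- array(FALSE, dim = c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  f <- reference_distance_field(m, c(10, 10, 10))
  expect_equal(f$values[5, 5, 8], 30)      # three x-steps
  expect_equal(f$values[5, 5, 5], 0)

  f2 <- reference_distance_field(m, c(40, 7, 7))
  expect_equal(f2$values[6, 5, 5], 40)     # one z-step costs 40 nm
  expect_equal(f2$values[5, 6, 6], sqrt(2) * 7)

  expect_error(reference_distance_field(array(FALSE, c(3, 3, 3)),
                                        c(10, 10, 10)), "empty")
})

test_that("the distance field matches brute force on random anisotropic masks", {
  set.seed(31)
  dims <- c(8, 7, 6); sp <- c(40, 7, 9)
  m <- array(runif(prod(dims)) < 0.08, dim = dims)
  m[2, 3, 4] <- TRUE
  f <- reference_distance_field(m, sp)
  refc <- perisyn:::mask_coords_nm(m, sp)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- (c(i, j, k) - 0.5) * sp
      expect_equal(f$values[i, j, k],
                   sqrt(min(colSums((t(refc) - p)^2))), tolerance = 1e-9)
    }
})

test_that("the sphere distance field is accurate to half a voxel diagonal", {
  fx <- sphere_fixture(10, R = 200, halfw = 320)
  f <- reference_distance_field(fx$ref, fx$sp)
  # at a point 300 nm from the center the distance to the ball is ~100
  n <- fx$dims[1]
  i <- which.min(abs((seq_len(n) - 0.5) * 10 - n * 10 / 2 - 300))
  d <- f$values[i, n / 2, n / 2]
  expect_lt(abs(d - (300 - 200)), sqrt(3) * 10 / 2 + 2)
})

test_that("V(r) equals brute-force enumeration exactly and curves accumulate", {
  syn <- generate_synapse(compact_params(), seed = 8)
  v <- syn$volume
  psd <- label_mask(v, "psd")
  astro <- label_mask(v, "astrocyte")
  field <- reference_distance_field(psd, v$spacing)
  radii <- seq(25, 175, by = 25)
  cu <- relational_curves(astro, field, radii, measures = "volume")

  dims <- dim(psd)
  voxvol <- prod(v$spacing)
  for (ri in c(2, 5, 7)) {
    r <- radii[ri]
    count <- 0L
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3]))
        if (astro[i, j, k] && field$values[i, j, k] <= r)
          count <- count + 1L
    expect_identical(cu$volume[ri], count * voxvol)
  }
  expect_true(all(diff(cu$volume) >= 0))
  expect_lte(max(cu$volume), attr(cu, "total_observed_volume"))
})

test_that("an empty observed object yields all-zero curves", {
  fx <- sphere_fixture(20, R = 100, halfw = 200)
  f <- reference_distance_field(fx$ref, fx$sp)
  cu <- relational_curves(array(FALSE, dim = fx$dims), f, c(50, 100))
  expect_true(all(cu$volume == 0))
  expect_true(all(cu$surface == 0))
  expect_true(all(cu$cut_area == 0))
  expect_true(all(cu$contour == 0))
  nz <- normalize_curves(cu)
  expect_true(all(nz$norm_volume == 0))
  expect_true(all(nz$norm_cut_area == 0))
})

test_that("the full complement saturates the normalized measures at 1", {
  fx <- sphere_fixture(20, R = 200, halfw = 320)
  f <- reference_distance_field(fx$ref, fx$sp)
  cu <- normalize_curves(relational_curves(!fx$ref, f, 100))
  expect_identical(cu$norm_volume, 1)
  expect_identical(cu$norm_cut_area, 1)
})

test_that("surface and volume measures are non-decreasing in r", {
  syn <- generate_synapse(compact_params(), seed = 13)
  v <- syn$volume
  f <- reference_distance_field(label_mask(v, "psd"), v$spacing)
  cu <- relational_curves(label_mask(v, "astrocyte"), f,
                          seq(25, 175, by = 25))
  expect_true(all(diff(cu$volume) >= 0))
  expect_true(all(diff(cu$surface) >= 0))
  expect_true(all(cu$cut_area >= 0))
  expect_true(all(cu$contour >= 0))
})

test_that("curves are invariant under 90-degree grid rotations", {
  fx <- sphere_fixture(10, R = 150, halfw = 260)
  obs <- (!fx$ref) & (fx$zc > 0)
  f <- reference_distance_field(fx$ref, fx$sp)
  cu <- relational_curves(obs, f, c(50, 100))

  perm <- c(3, 1, 2)
  ref_r <- aperm(fx$ref, perm)
  obs_r <- aperm(obs, perm)
  f_r <- reference_distance_field(ref_r, fx$sp)
  cu_r <- relational_curves(obs_r, f_r, c(50, 100))

  expect_identical(cu$volume, cu_r$volume)             # exact for counts
  expect_equal(cu$surface, cu_r$surface, tolerance = 0.01)
  expect_equal(cu$cut_area, cu_r$cut_area, tolerance = 0.01)
  expect_equal(cu$contour, cu_r$contour, tolerance = 0.01)
})

test_that("normalized curves are invariant under joint scaling of phantom and grid", {
  a <- sphere_fixture(20, R = 200, halfw = 320)
  b <- sphere_fixture(10, R = 100, halfw = 160)   # same voxel geometry
  fa <- reference_distance_field(a$ref, a$sp)
  fb <- reference_distance_field(b$ref, b$sp)
  # the largest radius truncates at the box on purpose: normalization
  # denominators live on the same grid, so the truncation cancels
  ca <- suppressWarnings(
    normalize_curves(relational_curves((!a$ref) & (a$zc > 0), fa,
                                       c(100, 200))))
  cb <- suppressWarnings(
    normalize_curves(relational_curves((!b$ref) & (b$zc > 0), fb,
                                       c(50, 100))))
  for (col in c("norm_volume", "norm_cut_area", "norm_surface"))
    expect_equal(ca[[col]], cb[[col]], tolerance = 1e-9)
  # contour denominator is linear in length, so it scales as 1/2
  expect_equal(ca$contour, 2 * cb$contour, tolerance = 1e-9)
})

test_that("restrict_window subsets the curve and validates bounds", {
  cu <- fake_curve(1:7, radii = seq(25, 175, by = 25))
  w <- restrict_window(cu, 25, 175)
  expect_identical(nrow(w), 7L)
  single <- restrict_window(cu, 100, 100)
  expect_identical(nrow(single), 1L)
  expect_identical(single$radius, 100)
  expect_error(restrict_window(fake_curve(1:6, seq(25, 150, 25)), 25, 175),
               "span")
  expect_identical(attr(w, "roi_id"), "fake")
})

test_that("mask disjointness and radii grids are validated", {
  fx <- sphere_fixture(20, R = 100, halfw = 200)
  f <- reference_distance_field(fx$ref, fx$sp)
  expect_error(relational_curves(fx$ref, f, 50), "disjoint")
  expect_error(relational_curves(!fx$ref, f, c(100, 50)), "increasing")
  expect_error(relational_curves(!fx$ref, f, 1500), "1000")
})
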