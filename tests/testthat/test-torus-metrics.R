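test_that("the slab phantom reproduces the analytic gap", {
  fx <- slab_fixture(gap = 60, h = 10)
  md <- min_distance_psd_to_astrocyte(fx$a, fx$b, fx$sp)
  expect_lt(abs(md - 60), 10 + 1e-9)
  # symmetry in swapping the two masks
  expect_equal(md, min_distance_psd_to_astrocyte(fx$b, fx$a, fx$sp))
})

test_that("touching structures are at most one voxel pitch apart", {
  fx <- slab_fixture(gap = 0, h = 10)
  touching <- min_distance_psd_to_astrocyte(fx$a, fx$b, fx$sp)
  expect_lte(touching, 10)
  expect_error(min_distance_psd_to_astrocyte(array(FALSE, dim(fx$a)),
                                             fx$b, fx$sp), "empty")
})

test_that("astrocyte outside the torus yields the infinity sentinel", {
  h <- 10
  # PSD disc at the center, normal +z
  psd <- disc_mask(radius = 100, thickness = 30, h = h, halfw = 300)
  n <- dim(psd)[1]
  vol_arr <- array(0L, dim = dim(psd))
  lm <- default_label_map()
  vol_arr[psd] <- lm[["psd"]]
  # astrocyte blob far along +z: inside the box, outside the torus slab
  zc <- array((seq_len(n) - (n + 1) / 2) * h, dim = dim(psd))
  blob <- zc > 250 & zc < 290
  vol_arr[blob] <- lm[["astrocyte"]]
  vol <- labeled_volume(vol_arr, c(h, h, h))
  fr <- fit_psd_frame(psd, vol$spacing)
  reg <- build_torus_region(fr, vol)
  astro <- label_mask(vol, "astrocyte")
  expect_identical(min_distance_psd_to_astrocyte(psd, astro, vol$spacing,
                                                 region = reg), Inf)
  # without the domain restriction the distance is finite
  expect_lt(min_distance_psd_to_astrocyte(psd, astro, vol$spacing), Inf)
})

test_that("astrocyte volume in the torus saturates at the torus volume", {
  syn <- generate_synapse(compact_params(), seed = 4)
  v <- syn$volume
  fr <- fit_psd_frame(label_mask(v, "psd"), v$spacing)
  reg <- build_torus_region(fr, v)
  astro <- label_mask(v, "astrocyte")
  av <- astro_volume_in_torus(astro, reg, v$spacing)
  tv <- sum(reg$mask) * prod(v$spacing)
  expect_gte(av, 0)
  expect_lte(av, tv)
  # no astrocyte -> 0; astrocyte filling the torus -> the torus volume
  expect_equal(astro_volume_in_torus(array(FALSE, dim(astro)), reg,
                                     v$spacing), 0)
  expect_equal(astro_volume_in_torus(reg$mask, reg, v$spacing), tv)
})

test_that("full-shell astrocyte volume in the torus matches numeric integration", {
  p <- synapse_params(head_radius = 200, astro_gap = 40,
                      astro_thickness = 50, astro_coverage = 1,
                      psd_cap_half_angle = 30, spacing = c(10, 10, 10),
                      box_margin = 120)
  syn <- generate_synapse(p, seed = 1)
  v <- syn$volume
  psd <- label_mask(v, "psd")
  fr <- fit_psd_frame(psd, v$spacing)
  reg <- build_torus_region(fr, v)
  av <- astro_volume_in_torus(label_mask(v, "astrocyte"), reg, v$spacing)

  # independent oracle: fine midpoint integration of the shell/annulus
  # intersection in cylindrical coordinates about the pole axis
  R1 <- 200 + 40; R2 <- R1 + 50
  z0 <- unname(fr$barycenter["z"]) - unname(syn$truth$center["z"])
  step <- 1
  rho <- seq(reg$r_inner + step / 2, reg$r_outer - step / 2, by = step)
  zz <- seq(z0 - 150 + step / 2, z0 + 150 - step / 2, by = step)
  rr2 <- outer(rho^2, zz^2, "+")
  inside <- rr2 >= R1^2 & rr2 <= R2^2
  oracle <- sum((2 * pi * rho * step * step) *
                  rowSums(inside))
  expect_equal(av, oracle, tolerance = 0.05)
})

test_that("the apposition filter partitions ROIs at the inclusive threshold", {
  mk_roi <- function(id, md) {
    # metric rows are what the filter consumes; ROI carries identity
    syn <- generate_synapse(compact_params(astro_coverage = 0.5), seed = 1)
    synapse_roi(syn$volume, roi_id = id, group = "WT")
  }
  rois <- lapply(sprintf("r%02d", 1:10), mk_roi)
  metrics <- data.frame(
    roi_id = sprintf("r%02d", 1:10),
    min_distance = c(100, 40, 101, 130, 60, 80, 150, 20, 95, 99.9))
  flt <- filter_rois(rois, metrics, threshold = 100)
  expect_identical(unname(flt$counts), c(10L, 7L, 3L))
  expect_true(flt$metrics$included[flt$metrics$roi_id == "r01"])  # == 100
  expect_false(flt$metrics$included[flt$metrics$roi_id == "r03"]) # 101
  expect_match(flt$metrics$exclusion_reason[flt$metrics$roi_id == "r04"],
               "100 nm")
  expect_true(all(vapply(flt$included, function(r) isTRUE(r$included),
                         logical(1))))

  # Inf distances (no astrocyte in domain) are excluded
  metrics$min_distance[1] <- Inf
  flt2 <- filter_rois(rois, metrics)
  expect_identical(unname(flt2$counts[["included"]]), 6L)
})

test_that("group scalar summaries report mean and SEM per group", {
  metrics <- data.frame(
    roi_id = sprintf("r%d", 1:6), group = rep(c("WT", "R6/2"), each = 3),
    psd_volume = c(1, 2, 3, 4, 5, 6), min_distance = 1:6,
    astro_volume = 1:6)
  s <- summarize_torus_metrics(metrics)
  wt <- s[s$group == "WT" & s$metric == "psd_volume", ]
  expect_equal(wt$mean, 2)
  expect_equal(wt$sem, sd(1:3) / sqrt(3))
  expect_identical(nrow(s), 6L)
})
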