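test_that("the AUC distance equals the hand-computed rectangle area", {
  a <- lapply(1:3, function(i) fake_curve(rep(2, 7)))
  b <- lapply(1:3, function(i) fake_curve(rep(5, 7)))
  t_prime <- curve_auc_distance(a, b, window = c(25, 175),
                                measure = "volume", normalized = FALSE)
  expect_equal(t_prime, 3 * 150)           # |2 - 5| x 150 nm
  # symmetry under swapping group labels
  expect_equal(curve_auc_distance(b, a, window = c(25, 175),
                                  measure = "volume", normalized = FALSE),
               t_prime)
  # identical mean curves -> 0
  expect_equal(curve_auc_distance(a, a, window = c(25, 175),
                                  measure = "volume", normalized = FALSE), 0)
})

test_that("net-mode AUC takes the absolute value of the signed integral", {
  up <- fake_curve(c(rep(2, 4), rep(8, 3)))
  down <- fake_curve(c(rep(8, 4), rep(2, 3)))
  abs_d <- curve_auc_distance(list(up), list(down), c(25, 175),
                              "volume", FALSE, mode = "abs")
  net_d <- curve_auc_distance(list(up), list(down), c(25, 175),
                              "volume", FALSE, mode = "net")
  expect_gt(abs_d, net_d)                  # cancellation only in net mode
})

test_that("identical curve multisets give t' = 0 and p = 1", {
  g <- lapply(1:4, function(i) fake_curve(i * (1:7)))
  pr <- permutation_test(g, g, n_perm = 200, seed = 5,
                         measure = "volume", normalized = FALSE)
  expect_equal(pr$observed_distance, 0)
  expect_equal(pr$p_value, 1)
})

test_that("permutation results are deterministic in (inputs, seed)", {
  set.seed(99)
  a <- lapply(1:5, function(i) fake_curve(rnorm(7, 1)))
  b <- lapply(1:5, function(i) fake_curve(rnorm(7, 1.5)))
  p1 <- permutation_test(a, b, n_perm = 300, seed = 17,
                         measure = "volume", normalized = FALSE)
  p2 <- permutation_test(a, b, n_perm = 300, seed = 17,
                         measure = "volume", normalized = FALSE)
  expect_identical(p1$null_distances, p2$null_distances)
  expect_identical(p1$p_value, p2$p_value)
  p3 <- permutation_test(a, b, n_perm = 300, seed = 18,
                         measure = "volume", normalized = FALSE)
  expect_false(identical(p1$null_distances, p3$null_distances))
  expect_length(p1$null_distances, 300)
  expect_gt(p1$p_value, 0)
})

test_that("the permutation p value is invariant to joint monotone rescaling", {
  set.seed(7)
  a <- lapply(1:5, function(i) fake_curve(rnorm(7, 1)))
  b <- lapply(1:5, function(i) fake_curve(rnorm(7, 2)))
  scale_curve <- function(cu, f) { cu$volume <- cu$volume * f; cu }
  p1 <- permutation_test(a, b, n_perm = 400, seed = 3,
                         measure = "volume", normalized = FALSE)
  p2 <- permutation_test(lapply(a, scale_curve, f = 3.7),
                         lapply(b, scale_curve, f = 3.7),
                         n_perm = 400, seed = 3,
                         measure = "volume", normalized = FALSE)
  expect_identical(p1$p_value, p2$p_value)
})

test_that("permutation preconditions are enforced", {
  a <- lapply(1:5, function(i) fake_curve(rep(i, 7)))
  expect_error(permutation_test(a[1], a, n_perm = 200, seed = 1,
                                measure = "volume", normalized = FALSE),
               ">= 2")
  expect_warning(permutation_test(a, a, n_perm = 50, seed = 1,
                                  measure = "volume", normalized = FALSE),
                 "resolution")
  short <- lapply(1:3, function(i) fake_curve(1:6, radii = seq(25, 150, 25)))
  expect_error(permutation_test(a, short, n_perm = 200, seed = 1,
                                measure = "volume", normalized = FALSE),
               "radii")
})

test_that("scalar tests report Welch t and F as in the analysis scheme", {
  res <- scalar_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$t_p, 1)
  expect_equal(res$f_ratio, 1)

  # two shifted normal samples, n = 30, delta = 2 sd -> decisive rejection
  x <- perisyn:::with_preserved_seed(21, list(a = rnorm(30), b = rnorm(30, 2)))
  res2 <- scalar_tests(x$a, x$b)
  expect_lt(res2$t_p, 0.01)

  expect_error(scalar_tests(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(scalar_tests(1, c(1, 2)), ">= 2")
})

test_that("spine-class validation separates constructed size classes", {
  # thin heads 120 nm vs mushroom heads 240 nm (2x), 5 ROIs each
  mk <- function(head, id, cls) {
    p <- synapse_params(head_radius = head, psd_thickness = 25,
                        astro_gap = 40, astro_thickness = 40,
                        astro_coverage = 0.6, bouton_radius = 80,
                        cleft_width = 15, spacing = c(15, 15, 15),
                        box_margin = 190)
    syn <- generate_synapse(p, seed = id)
    synapse_roi(syn$volume, roi_id = sprintf("%s%02d", cls, id),
                group = if (id %% 2) "WT" else "R6/2", spine_class = cls,
                ground_truth = syn$truth)
  }
  rois <- c(lapply(1:5, function(i) mk(120 + 4 * i, i, "thin")),
            lapply(1:5, function(i) mk(240 + 8 * i, i, "mushroom")))
  res <- classify_validation(rois, radii = seq(25, 175, by = 25),
                             n_perm = 400, seed = 2)
  expect_s3_class(res$class_comparison, "PermutationResult")
  expect_lte(res$class_comparison$p_value, 0.05)
  expect_length(res$curves, 10)

  # single class present: comparison skipped, curves still emitted
  expect_warning(res1 <- classify_validation(rois[1:4],
                                             radii = seq(25, 175, 25),
                                             n_perm = 200, seed = 2),
                 NA)
  expect_null(res1$class_comparison)
  expect_length(res1$curves, 4)
})
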