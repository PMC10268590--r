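# Analytic fixtures built in code; all sizes in nm.

# Reference sphere of radius R centered in a cube of half-width halfw,
# isotropic spacing h. Returns the mask, spacing, dims and the z-coordinate
# array (centered at the sphere center) for carving half-spaces.
sphere_fixture <- function(h, R = 200, halfw = 352) {
  n <- as.integer(ceiling(2 * halfw / h))
  ax <- (seq_len(n) - 0.5) * h - n * h / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  list(ref = r2 <= R^2, sp = c(h, h, h), dims = c(n, n, n),
       zc = array(ax, dim = c(n, n, n)))
}

# Voxelized disc of given radius/thickness, lying perpendicular to `axis`
# (1 = z, 2 = y, 3 = x). The grid is odd-sized with a voxel center on the
# disc center so an r/thickness in whole voxels digitizes symmetrically.
disc_mask <- function(radius = 150, thickness = 30, h = 10, halfw = 220,
                      axis = 1) {
  n <- 2L * as.integer(ceiling(halfw / h)) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * h          # centers ..., -h, 0, h, ...
  ax2 <- ax^2
  grids <- list(
    outer(outer(ax2 * 0, ax2, "+"), ax2, "+"),   # in-plane r2 if axis = 1
    outer(outer(ax2, ax2 * 0, "+"), ax2, "+"),
    outer(outer(ax2, ax2, "+"), ax2 * 0, "+"))
  base <- array(ax, dim = c(n, n, n))            # varies along dim 1
  perp <- list(base,
               aperm(base, c(2, 1, 3)),          # varies along dim 2
               aperm(base, c(2, 3, 1)))          # varies along dim 3
  grids[[axis]] <= radius^2 & abs(perp[[axis]]) < thickness / 2
}

# Two parallel slabs (along z) separated by `gap` nm of background.
slab_fixture <- function(gap, h = 10, slab = 40, lateral = 200) {
  nz <- as.integer(ceiling((2 * slab + gap + 4 * h) / h))
  nl <- as.integer(ceiling(lateral / h))
  z <- (seq_len(nz) - 0.5) * h
  a <- array(FALSE, dim = c(nz, nl, nl))
  b <- array(FALSE, dim = c(nz, nl, nl))
  a[z <= slab, , ] <- TRUE
  b[z >= slab + gap & z <= 2 * slab + gap, , ] <- TRUE
  list(a = a, b = b, sp = c(h, h, h))
}

# Compact phantom preset used by the simulation studies (smaller head and
# coarser grid than the display-scale default, same topology).
compact_params <- function(...) {
  args <- utils::modifyList(
    list(head_radius = 150, psd_thickness = 30, astro_gap = 40,
         astro_thickness = 40, astro_coverage = 0.6, bouton_radius = 100,
         cleft_width = 15, spacing = c(15, 15, 15), box_margin = 180),
    list(...))
  do.call(synapse_params, args)
}

compact_group <- function(cov_mean = 0.6, head_mean = 150) {
  list(head_radius = c(head_mean, 25), astro_coverage = c(cov_mean, 0.12),
       astro_gap = c(40, 10))
}

# Thin-spine-scale phantom whose entire astrocyte shell lies within 175 nm
# of the PSD (the farthest shell point is ~168 nm from the cap edge), so
# solid-angle coverage maps linearly onto the normalized volume curve over
# the whole 25-175 nm analysis window. The coverage sweep and the
# permutation simulation studies run at this scale.
study_params <- function(...) {
  args <- utils::modifyList(
    list(head_radius = 70, psd_cap_half_angle = 30, psd_thickness = 20,
         astro_gap = 12, astro_thickness = 22, astro_coverage = 0.6,
         bouton_radius = 60, cleft_width = 12, spacing = c(10, 10, 10),
         box_margin = 180),
    list(...))
  do.call(synapse_params, args)
}

study_group <- function(cov_mean = 0.6) {
  list(head_radius = c(70, 10), astro_coverage = c(cov_mean, 0.12),
       astro_gap = c(12, 3))
}

# Normalized astrocyte volume curves for a list of ROIs (volume-only,
# mesh-free; the workhorse of the permutation simulations).
roi_volume_curves <- function(rois, radii = seq(25, 175, by = 25)) {
  lapply(rois, function(roi) {
    v <- roi$volume
    field <- reference_distance_field(label_mask(v, "psd"), v$spacing)
    normalize_curves(relational_curves(label_mask(v, "astrocyte"), field,
                                       radii, measures = "volume",
                                       roi_id = roi$roi_id))
  })
}

# One two-group cohort -> permutation result on normalized volume curves.
cohort_permutation <- function(seed, cov_a = 0.6, cov_b = 0.6,
                               n_per_group = 8, n_perm = 500) {
  spec <- cohort_spec(n_per_group = n_per_group,
                      groups = list(A = study_group(cov_a),
                                    B = study_group(cov_b)),
                      base_params = study_params(), seed = seed)
  rois <- generate_cohort(spec)
  curves <- roi_volume_curves(rois)
  groups <- vapply(rois, function(r) r$group, character(1))
  permutation_test(curves[groups == "A"], curves[groups == "B"],
                   n_perm = n_perm, seed = seed + 1L,
                   window = c(25, 175), measure = "volume",
                   normalized = TRUE)
}

# Fabricated MeasureCurve with a prescribed raw volume column (for the
# statistics unit tests, where curve provenance is irrelevant).
fake_curve <- function(values, radii = seq(25, 175, by = 25), id = "fake") {
  stopifnot(length(values) == length(radii))
  out <- data.frame(radius = radii, volume = values,
                    surface = NA_real_, cut_area = NA_real_,
                    contour = NA_real_, shell_volume = NA_real_,
                    shell_area = NA_real_, truncation = NA_real_)
  attr(out, "roi_id") <- id
  attr(out, "observed_label") <- "astrocyte"
  attr(out, "total_observed_volume") <- max(values)
  attr(out, "ref_volume") <- 1
  class(out) <- c("MeasureCurve", "data.frame")
  out
}

triangle_area_sum <- function(tri) sum(perisyn:::triangle_areas(tri))
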