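#' Geometry parameters for a synthetic tripartite-synapse phantom
#'
#' The phantom emulates the segmented structures of a single synapse: a
#' spherical spine head carrying a PSD (a spherical cap of the head surface,
#' thickened inward, so the head surface is the PSD's outer face), an
#' astrocytic process forming a partial spherical shell around the head at a
#' controllable standoff gap and solid-angle coverage, and a presynaptic
#' bouton apposed across the PSD. The shell sector is centered on the PSD
#' pole axis so that coverage concentrates at the synaptic periphery.
#'
#' @param head_radius Spine head radius, nm.
#' @param psd_cap_half_angle PSD cap half-angle from the pole axis, degrees,
#'   in (0, 90].
#' @param psd_thickness PSD thickness (radially inward from the head
#'   surface), nm.
#' @param astro_gap Standoff between head surface and astrocyte shell inner
#'   surface, nm; equals the true minimum PSD-to-astrocyte distance.
#' @param astro_thickness Astrocyte shell thickness, nm.
#' @param astro_coverage Fraction of the full solid angle covered by the
#'   shell, in `[0, 1]`; 0 means no astrocyte.
#' @param bouton_radius Presynaptic bouton radius, nm (decorative; clipped
#'   at the box boundary and never used by any measurement).
#' @param cleft_width Synaptic cleft width between head surface and bouton,
#'   nm.
#' @param spacing Voxel spacing in nm (z, y, x). Isotropic 10 nm default;
#'   `c(40, 7, 7)` mirrors a strongly anisotropic SBF-SEM acquisition.
#' @param box_margin Clearance between the astrocyte shell's outer surface
#'   and the box faces, nm; must be at least the largest dilation radius to
#'   be analyzed, or curves will be truncated by the box.
#' @param jitter_sd Gaussian perturbation (sd, nm) of the implicit surface
#'   threshold, adding boundary roughness; 0 keeps the geometry exact so
#'   analytic oracles apply.
#' @return Validated parameter list of class `SynapseGeometryParams`.
#' @export
synapse_params <- function(head_radius = 300, psd_cap_half_angle = 30,
                           psd_thickness = 30, astro_gap = 60,
                           astro_thickness = 60, astro_coverage = 0.5,
                           bouton_radius = 250, cleft_width = 20,
                           spacing = c(10, 10, 10), box_margin = 200,
                           jitter_sd = 0) {
  lens <- c(head_radius = head_radius, psd_thickness = psd_thickness,
            astro_gap = astro_gap, astro_thickness = astro_thickness,
            bouton_radius = bouton_radius, cleft_width = cleft_width,
            box_margin = box_margin)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad))
    stopf("lengths must be positive: %s", paste(bad, collapse = ", "))
  if (!is.finite(astro_coverage) || astro_coverage < 0 || astro_coverage > 1)
    stopf("astro_coverage must be in [0, 1]")
  if (!is.finite(psd_cap_half_angle) || psd_cap_half_angle <= 0 ||
      psd_cap_half_angle > 90)
    stopf("psd_cap_half_angle must be in (0, 90] degrees")
  if (psd_thickness >= head_radius)
    stopf("psd_thickness must be smaller than head_radius")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive nm values (z, y, x)")
  if (!is.finite(jitter_sd) || jitter_sd < 0)
    stopf("jitter_sd must be non-negative")
  structure(list(head_radius = head_radius,
                 psd_cap_half_angle = psd_cap_half_angle,
                 psd_thickness = psd_thickness, astro_gap = astro_gap,
                 astro_thickness = astro_thickness,
                 astro_coverage = astro_coverage,
                 bouton_radius = bouton_radius, cleft_width = cleft_width,
                 spacing = as.numeric(spacing), box_margin = box_margin,
                 jitter_sd = jitter_sd),
            class = "SynapseGeometryParams")
}

# Analytic barycenter offset (along the pole axis) of the PSD cap region:
# radial band [R - t, R], polar angle <= alpha, density uniform.
psd_cap_barycenter_z <- function(R, t, alpha_deg) {
  a <- alpha_deg * pi / 180
  num <- 3 * (R^4 - (R - t)^4) * sin(a)^2
  den <- 8 * (R^3 - (R - t)^3) * (1 - cos(a))
  num / den
}

#' Generate a voxelized tripartite-synapse phantom with ground truth
#'
#' Voxelizes the geometry of [synapse_params()] onto an anisotropic grid.
#' Labels are pairwise disjoint by construction (priority: psd, spine,
#' astrocyte, axon). Identical `(params, seed)` yield identical volumes; the
#' seed only matters when `jitter_sd > 0`.
#'
#' @param params A `SynapseGeometryParams`.
#' @param seed Integer seed for boundary jitter.
#' @param box_halfwidth Optional explicit half-width of the cubic box in nm;
#'   a geometry error names the violated margin if the phantom (head +
#'   astrocyte shell + box_margin) does not fit.
#' @return List with `volume` (a `LabeledVolume`) and `truth`, a list
#'   recording true astro_coverage, astro_gap, PSD chord radius (the R_max
#'   analog), analytic PSD barycenter, and the generator parameters.
#' @export
generate_synapse <- function(params, seed = 1L, box_halfwidth = NULL) {
  stopifnot(inherits(params, "SynapseGeometryParams"))
  p <- params
  reach <- p$head_radius + p$astro_gap + p$astro_thickness
  need <- reach + p$box_margin
  if (is.null(box_halfwidth)) {
    half <- need
  } else {
    if (box_halfwidth < need)
      stopf(paste0("phantom exceeds box: need half-width >= %.1f nm ",
                   "(head %.0f + gap %.0f + shell %.0f + margin %.0f), got %.1f"),
            need, p$head_radius, p$astro_gap, p$astro_thickness,
            p$box_margin, box_halfwidth)
    half <- box_halfwidth
  }
  dims <- pmax(2L, as.integer(ceiling(2 * half / p$spacing)))
  ctr <- dims * p$spacing / 2

  axes <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * p$spacing[a] - ctr[a])
  r2 <- outer(outer(axes[[1]]^2, axes[[2]]^2, "+"), axes[[3]]^2, "+")
  rho <- sqrt(r2)
  zc <- array(axes[[1]], dim = dims)
  cos_theta <- zc / pmax(rho, 1e-9)

  if (p$jitter_sd > 0) {
    rj <- rho + with_preserved_seed(seed,
            array(rnorm(prod(dims), 0, p$jitter_sd), dim = dims))
  } else {
    rj <- rho
  }

  R <- p$head_radius
  cos_cap <- cos(p$psd_cap_half_angle * pi / 180)
  head <- rj <= R
  psd <- head & (rj >= R - p$psd_thickness) & (cos_theta >= cos_cap)
  spine <- head & !psd

  if (p$astro_coverage > 0) {
    cos_cov <- 1 - 2 * p$astro_coverage
    astro <- (rj >= R + p$astro_gap) &
             (rj <= R + p$astro_gap + p$astro_thickness) &
             (cos_theta >= cos_cov)
  } else {
    astro <- array(FALSE, dim = dims)
  }

  zoff <- R + p$cleft_width + p$bouton_radius
  rb2 <- (zc - zoff)^2 + (r2 - zc^2)
  axon <- rb2 <= p$bouton_radius^2 & !head & !astro

  lm <- default_label_map()
  labels <- array(0L, dim = dims)
  labels[spine] <- lm[["spine"]]
  labels[psd] <- lm[["psd"]]
  labels[astro] <- lm[["astrocyte"]]
  labels[axon] <- lm[["axon"]]

  vol <- labeled_volume(labels, p$spacing, lm)
  truth <- list(
    astro_coverage = p$astro_coverage,
    astro_gap = p$astro_gap,
    chord_radius = R * sin(p$psd_cap_half_angle * pi / 180),
    psd_barycenter = c(z = ctr[1] + psd_cap_barycenter_z(R, p$psd_thickness,
                                                         p$psd_cap_half_angle),
                       y = ctr[2], x = ctr[3]),
    head_radius = R,
    center = stats::setNames(ctr, c("z", "y", "x")),
    params = p, seed = seed
  )
  list(volume = vol, truth = truth)
}

#' Specify a two-group (or multi-group) synthetic cohort
#'
#' Per-group distributions (mean, sd) for head radius, astrocyte coverage
#' and astrocyte gap; each draw is truncated at its bounds so every sampled
#' parameter set is valid. Spine class is assigned by a declared synthetic
#' convention: heads below `class_threshold` nm are "thin", others
#' "mushroom".
#'
#' @param n_per_group ROIs per group (>= 1).
#' @param groups Named list; each element a list with optional numeric
#'   length-2 entries `head_radius`, `astro_coverage`, `astro_gap` giving
#'   `c(mean, sd)`. Defaults: head 250 (sd 50) nm, coverage 0.6 (sd 0.15),
#'   gap 60 (sd 15) nm.
#' @param base_params `SynapseGeometryParams` supplying all remaining
#'   geometry (thicknesses, spacing, margins).
#' @param class_threshold Head-radius split between thin and mushroom, nm.
#' @param seed Integer seed; cohorts are reproducible under it.
#' @return An object of class `CohortSpec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = list("WT" = list(), "R6/2" = list()),
                        base_params = synapse_params(),
                        class_threshold = 250, seed = 1L) {
  if (n_per_group < 1) stopf("n_per_group must be >= 1")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stopf("groups must be a named list")
  defaults <- list(head_radius = c(250, 50), astro_coverage = c(0.6, 0.15),
                   astro_gap = c(60, 15))
  groups <- lapply(groups, function(g) {
    g <- utils::modifyList(defaults, g)
    for (nm in names(defaults)) {
      v <- g[[nm]]
      if (length(v) != 2 || any(!is.finite(v)))
        stopf("group distribution '%s' must be c(mean, sd)", nm)
      if (v[2] < 0) stopf("degenerate distribution: sd < 0 for '%s'", nm)
    }
    g
  })
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 base_params = base_params,
                 class_threshold = class_threshold, seed = as.integer(seed)),
            class = "CohortSpec")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a cohort of synthetic synapse ROIs
#'
#' Draws per-ROI geometry from the group distributions of a [cohort_spec()],
#' voxelizes each phantom, and returns `SynapseROI` objects with ground
#' truth retained. Reproducible under the cohort seed; per-ROI voxelization
#' seeds are derived from it so that extending the cohort does not perturb
#' earlier ROIs.
#'
#' @param spec A `CohortSpec`.
#' @return List of `SynapseROI`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  bp <- spec$base_params
  min_sp <- min(bp$spacing)
  draws <- with_preserved_seed(spec$seed, {
    out <- list()
    for (g in names(spec$groups)) {
      gd <- spec$groups[[g]]
      n <- spec$n_per_group
      out[[g]] <- data.frame(
        head_radius = rnorm_trunc(n, gd$head_radius[1], gd$head_radius[2],
                                  lo = max(4 * min_sp, bp$psd_thickness + min_sp),
                                  hi = Inf),
        astro_coverage = rnorm_trunc(n, gd$astro_coverage[1],
                                     gd$astro_coverage[2], 0, 1),
        astro_gap = rnorm_trunc(n, gd$astro_gap[1], gd$astro_gap[2],
                                lo = min_sp, hi = Inf)
      )
    }
    out
  })
  rois <- list()
  gi <- 0L
  for (g in names(spec$groups)) {
    gi <- gi + 1L
    d <- draws[[g]]
    for (i in seq_len(spec$n_per_group)) {
      p <- synapse_params(
        head_radius = d$head_radius[i],
        psd_cap_half_angle = bp$psd_cap_half_angle,
        psd_thickness = bp$psd_thickness,
        astro_gap = d$astro_gap[i],
        astro_thickness = bp$astro_thickness,
        astro_coverage = d$astro_coverage[i],
        bouton_radius = bp$bouton_radius, cleft_width = bp$cleft_width,
        spacing = bp$spacing, box_margin = bp$box_margin,
        jitter_sd = bp$jitter_sd)
      roi_seed <- (spec$seed + 7919L * gi + i) %% .Machine$integer.max
      syn <- generate_synapse(p, seed = roi_seed)
      cls <- if (d$head_radius[i] < spec$class_threshold) "thin" else "mushroom"
      rois[[length(rois) + 1L]] <- synapse_roi(
        syn$volume, roi_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", g), i),
        group = g, spine_class = cls, ground_truth = syn$truth,
        groups = names(spec$groups))
    }
  }
  rois
}
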