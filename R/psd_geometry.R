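# Voxel-center coordinates (nm) of TRUE voxels, rows = (z, y, x).
mask_coords_nm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 0.5, 2, spacing, "*")
}

# Exact maximum pairwise distance between rows of P (n x 3), chunked so the
# cross-distance matrix never exceeds ~2e6 entries. The diameter endpoints
# are extreme points, so callers pass boundary voxels only.
max_pairwise_distance <- function(P) {
  n <- nrow(P)
  if (n < 2) return(0)
  sq <- rowSums(P^2)
  best <- 0
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    d2 <- outer(sq[s:e], sq, "+") - 2 * P[s:e, , drop = FALSE] %*% t(P)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Fit the PSD reference frame
#'
#' The frame anchors all PSD-relative measurements: its barycenter is the
#' volume-weighted centroid of PSD voxel centers; `r_max` is half the PSD's
#' longest axis (half the maximum pairwise distance between voxel centers,
#' computed on boundary voxels); the disc normal is the principal direction
#' of least variance of the voxel-center cloud, the PSD being a flat,
#' disc-like structure. The normal's sign is chosen toward the
#' astrocyte-free half-space when an astrocyte mask is supplied and
#' informative, else toward +z.
#'
#' @param psd_mask Logical 3D array of PSD voxels (non-empty).
#' @param spacing Per-axis nm (z, y, x).
#' @param astro_mask Optional astrocyte mask used only to orient the normal.
#' @return An object of class `PSDFrame` with fields `barycenter`, `r_max`,
#'   `normal` (unit 3-vector, (z, y, x)), `psd_volume` (nm^3).
#' @export
fit_psd_frame <- function(psd_mask, spacing, astro_mask = NULL) {
  if (!any(psd_mask)) stopf("PSD mask is empty")
  coords <- mask_coords_nm(psd_mask, spacing)
  n <- nrow(coords)
  barycenter <- colMeans(coords)
  psd_volume <- n * prod(spacing)

  if (n == 1) {
    warnf("single-voxel PSD: degenerate frame with r_max = 0")
    normal <- c(1, 0, 0)
    r_max <- 0
  } else {
    bnd <- boundary_voxels(psd_mask)
    r_max <- max_pairwise_distance(mask_coords_nm(bnd, spacing)) / 2
    cv <- cov(coords)
    eg <- eigen(cv, symmetric = TRUE)
    normal <- eg$vectors[, which.min(eg$values)]
    normal <- normal / sqrt(sum(normal^2))
  }

  flip <- FALSE
  if (!is.null(astro_mask) && any(astro_mask)) {
    ac <- colMeans(mask_coords_nm(astro_mask, spacing))
    s <- sum(normal * (ac - barycenter))
    if (abs(s) > 1e-9) flip <- s > 0   # point away from the astrocyte
    else flip <- normal[1] < 0
  } else {
    flip <- normal[1] < 0
  }
  if (flip) normal <- -normal

  structure(list(barycenter = stats::setNames(barycenter, c("z", "y", "x")),
                 r_max = r_max,
                 normal = stats::setNames(normal, c("z", "y", "x")),
                 psd_volume = psd_volume),
            class = "PSDFrame")
}

#' @export
print.PSDFrame <- function(x, ...) {
  cat(sprintf(paste0("PSDFrame: barycenter (%.1f, %.1f, %.1f) nm, ",
                     "r_max %.1f nm, volume %.3g nm^3\n"),
              x$barycenter[1], x$barycenter[2], x$barycenter[3],
              x$r_max, x$psd_volume))
  invisible(x)
}

#' Build the PSD-anchored torus analysis region
#'
#' The torus is the cylindrical annulus about the PSD frame: radial bounds
#' `inner_factor * r_max` to `outer_factor * r_max` (defaults 0.75 and 1.5)
#' and total depth 300 nm centered on the barycenter plane. PSD voxels are
#' excluded from the mask. A warning reports the truncated fraction when
#' the analytic annulus extends beyond the volume.
#'
#' @param frame A `PSDFrame` with `r_max > 0`.
#' @param volume The `LabeledVolume` defining the grid.
#' @param depth Torus depth (total thickness along the normal), nm.
#' @param inner_factor,outer_factor Radial bounds as multiples of `r_max`;
#'   `0 < inner_factor < outer_factor`.
#' @return An object of class `TorusRegion` with the voxel `mask`, bounds
#'   and estimated `truncated_fraction`.
#' @export
build_torus_region <- function(frame, volume, depth = 300,
                               inner_factor = 0.75, outer_factor = 1.5) {
  stopifnot(inherits(frame, "PSDFrame"), inherits(volume, "LabeledVolume"))
  if (frame$r_max <= 0)
    stopf("degenerate PSD frame: r_max must be > 0 to build a torus")
  if (depth <= 0) stopf("torus depth must be positive")
  if (!(inner_factor > 0 && inner_factor < outer_factor))
    stopf("need 0 < inner_factor < outer_factor")
  r_in <- inner_factor * frame$r_max
  r_out <- outer_factor * frame$r_max

  dims <- dim(volume$labels)
  sp <- volume$spacing
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * sp[a] -
                 frame$barycenter[a])
  nrm <- unname(frame$normal)
  # separable fields: h = (p - b) . n ; d2 = |p - b|^2 ; rho^2 = d2 - h^2
  h <- outer(outer(ax[[1]] * nrm[1], ax[[2]] * nrm[2], "+"),
             ax[[3]] * nrm[3], "+")
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  rho2 <- pmax(d2 - h^2, 0)

  annulus <- rho2 >= r_in^2 & rho2 <= r_out^2 & abs(h) <= depth / 2
  psd <- label_mask(volume, "psd")
  mask <- annulus & !psd

  analytic <- pi * (r_out^2 - r_in^2) * depth
  measured <- sum(annulus) * prod(sp)
  truncated_fraction <- max(0, 1 - measured / analytic)

  # Geometric reach test: does the annulus bounding box leave the volume?
  reach <- sqrt(r_out^2 + (depth / 2)^2)
  box_hi <- dims * sp
  if (any(frame$barycenter - reach < 0) ||
      any(frame$barycenter + reach > box_hi)) {
    warnf("torus may be truncated by the volume boundary (truncated fraction ~%.3f)",
          truncated_fraction)
  }

  structure(list(frame = frame, r_inner = r_in, r_outer = r_out,
                 depth = depth, mask = mask,
                 truncated_fraction = truncated_fraction),
            class = "TorusRegion")
}

#' @export
print.TorusRegion <- function(x, ...) {
  cat(sprintf(paste0("TorusRegion: radial [%.1f, %.1f] nm, depth %.0f nm, ",
                     "%d voxels (truncated fraction %.3f)\n"),
              x$r_inner, x$r_outer, x$depth, sum(x$mask),
              x$truncated_fraction))
  invisible(x)
}
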