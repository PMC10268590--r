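#' Anisotropic Euclidean distance field from a reference object
#'
#' Exact distance (nm) from every voxel center to the nearest reference
#' voxel center; zero exactly on the reference. The sublevel set
#' `{values <= r}` is the r-parallel set of the reference, whose growth
#' defines the dilation radii of the relational measures.
#'
#' @param ref_mask Logical 3D array of the reference object Y (non-empty).
#' @param spacing Per-axis nm (z, y, x).
#' @param reference_label Name recorded on the field (e.g. "psd").
#' @return An object of class `DistanceField` with fields `values`
#'   (numeric 3D array, nm), `spacing`, `reference_label`, and the
#'   reference volume `ref_volume` (nm^3).
#' @export
reference_distance_field <- function(ref_mask, spacing,
                                     reference_label = "psd") {
  if (!any(ref_mask)) stopf("reference mask is empty")
  vals <- distance_to_mask(ref_mask, spacing)
  structure(list(values = vals, spacing = as.numeric(spacing),
                 reference_label = reference_label,
                 ref_volume = sum(ref_mask) * prod(spacing)),
            class = "DistanceField")
}

#' @export
print.DistanceField <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("DistanceField to '%s': %d x %d x %d voxels, range [0, %.1f] nm\n",
              x$reference_label, d[1], d[2], d[3], max(x$values)))
  invisible(x)
}

# Triangle areas of an n x 9 triangle-soup matrix.
triangle_areas <- function(tri) {
  if (nrow(tri) == 0) return(numeric(0))
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

triangle_centroids <- function(tri) {
  (tri[, 1:3, drop = FALSE] + tri[, 4:6, drop = FALSE] +
     tri[, 7:9, drop = FALSE]) / 3
}

# Triangulated isosurface {field = level} via marching tetrahedra.
isosurface_mesh <- function(values, spacing, level) {
  mtetra_cpp(as.numeric(values), as.integer(dim(values)),
             as.numeric(spacing), level)
}

# Trilinear sample of a numeric array at points (n x 3 nm, (z,y,x)).
sample_field <- function(values, spacing, pts) {
  interp_trilinear_cpp(as.numeric(values), as.integer(dim(values)),
                       as.numeric(spacing), pts)
}

# Nearest-voxel membership of points in a logical mask.
points_in_mask <- function(mask, spacing, pts) {
  d <- dim(mask)
  idx <- sapply(1:3, function(a)
    pmin(pmax(round(pts[, a] / spacing[a] + 0.5), 1), d[a]))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  mask[cbind(idx[, 1], idx[, 2], idx[, 3])]
}

# Total length of the level-set polyline of vertex values `v` (n x 3, one
# column per triangle vertex) on a triangle soup: per triangle, the level
# crossing is the segment joining linear interpolations on the two crossed
# edges.
mesh_isoline_length <- function(tri, v, level) {
  if (nrow(tri) == 0) return(0)
  s <- v > level
  nin <- rowSums(s)
  cross <- nin == 1L | nin == 2L
  if (!any(cross)) return(0)
  tri <- tri[cross, , drop = FALSE]
  v <- v[cross, , drop = FALSE]
  lone_hi <- rowSums(v > level) == 1L
  # permute so vertex 1 is the lone vertex on its side of the level
  lone <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    side <- v[i, ] > level
    lone[i] <- if (lone_hi[i]) which(side) else which(!side)
  }
  vidx <- function(m) (m - 1L) * 3L
  P <- function(k, col) tri[cbind(seq_len(nrow(tri)), vidx(k) + col)]
  Vv <- function(k) v[cbind(seq_len(nrow(v)), k)]
  o1 <- ifelse(lone == 1L, 2L, ifelse(lone == 2L, 1L, 1L))
  o2 <- ifelse(lone == 3L, 2L, 3L)
  f0 <- Vv(lone); f1 <- Vv(o1); f2 <- Vv(o2)
  t1 <- (level - f0) / (f1 - f0)
  t2 <- (level - f0) / (f2 - f0)
  seg2 <- 0
  for (col in 1:3) {
    a <- P(lone, col) + t1 * (P(o1, col) - P(lone, col))
    b <- P(lone, col) + t2 * (P(o2, col) - P(lone, col))
    seg2 <- seg2 + (a - b)^2
  }
  sum(sqrt(seg2[is.finite(seg2)]))
}

# Area of the r-parallel sublevel set clipped by the box faces: counts
# voxel faces on the 6 volume faces where field <= r.
box_face_area_below <- function(values, spacing, r) {
  d <- dim(values)
  a <- 0
  a <- a + sum(values[1, , ] <= r) * spacing[2] * spacing[3]
  a <- a + sum(values[d[1], , ] <= r) * spacing[2] * spacing[3]
  a <- a + sum(values[, 1, ] <= r) * spacing[1] * spacing[3]
  a <- a + sum(values[, d[2], ] <= r) * spacing[1] * spacing[3]
  a <- a + sum(values[, , 1] <= r) * spacing[1] * spacing[2]
  a <- a + sum(values[, , d[3]] <= r) * spacing[1] * spacing[2]
  a
}

#' Relational shape curves of an observed object around a reference
#'
#' For each dilation radius r, measures the observed object X against the
#' r-parallel set Y^r of the reference (the sublevel set of the distance
#' field): cumulative volume `V(r)` of X within Y^r (voxel counting);
#' surface area `S(r)` of X's boundary mesh within Y^r (triangles kept
#' where the centroid's field value is <= r); cut area `A_perp(r)`, the
#' area of the dilated isosurface `{field = r}` restricted to X; and
#' contour `C(r)`, the length of the intersection polyline of X's boundary
#' with the isosurface. Surface estimators are mesh-based (marching
#' tetrahedra) rather than voxel-face counts, which systematically
#' overestimate smooth areas. Normalization denominators (shell volume and
#' full isosurface area) are computed on the same grid so box truncation
#' cancels in the normalized curves; the truncated fraction of the dilated
#' surface is recorded per radius.
#'
#' @param observed_mask Logical 3D array of X; disjoint from the reference.
#' @param field A `DistanceField` from [reference_distance_field()].
#' @param radii Increasing dilation radii in nm, max 1000.
#' @param measures Which measures to compute; volume-only runs skip all
#'   meshing (used by large simulation studies).
#' @param observed_label,roi_id Metadata carried on the curve.
#' @return A `MeasureCurve`: data frame with one row per radius and columns
#'   radius, volume, surface, cut_area, contour, shell_volume, shell_area,
#'   truncation; attributes `roi_id`, `observed_label`,
#'   `total_observed_volume`, `ref_volume`.
#' @export
relational_curves <- function(observed_mask, field, radii,
                              measures = c("volume", "surface",
                                           "cut_area", "contour"),
                              observed_label = "astrocyte", roi_id = NA) {
  stopifnot(inherits(field, "DistanceField"))
  measures <- match.arg(measures, several.ok = TRUE)
  if (length(radii) < 1 || any(diff(radii) <= 0))
    stopf("radii must be strictly increasing")
  if (max(radii) > 1000)
    stopf("radii must not exceed 1000 nm")
  if (any(radii < 0)) stopf("radii must be non-negative")
  vals <- field$values
  sp <- field$spacing
  if (!identical(dim(observed_mask), dim(vals)))
    stopf("observed mask and distance field have different dimensions")
  if (any(observed_mask & vals == 0))
    stopf("observed and reference masks must be disjoint")

  voxvol <- prod(sp)
  nr <- length(radii)
  empty_observed <- !any(observed_mask)

  # cumulative volume by voxel counting; shell volume on the same grid
  fv_obs <- vals[observed_mask]
  fv_bg <- vals[vals > 0]
  volume <- vapply(radii, function(r) sum(fv_obs <= r) * voxvol, numeric(1))
  shell_volume <- vapply(radii, function(r) sum(fv_bg <= r) * voxvol,
                         numeric(1))

  surface <- rep(NA_real_, nr)
  cut_area <- rep(NA_real_, nr)
  contour <- rep(NA_real_, nr)
  shell_area <- rep(NA_real_, nr)
  truncation <- rep(NA_real_, nr)

  need_mesh <- any(c("surface", "cut_area", "contour") %in% measures)
  if (need_mesh) {
    if (!empty_observed &&
        any(c("surface", "contour") %in% measures)) {
      obs_mesh <- isosurface_mesh(observed_mask + 0, sp, 0.5)
      obs_areas <- triangle_areas(obs_mesh)
      if ("surface" %in% measures) {
        cent_vals <- sample_field(vals, sp, triangle_centroids(obs_mesh))
      }
      if ("contour" %in% measures && nrow(obs_mesh) > 0) {
        vert_vals <- sapply(1:3, function(k)
          sample_field(vals, sp, obs_mesh[, (k - 1) * 3 + (1:3),
                                          drop = FALSE]))
        if (is.null(dim(vert_vals)))
          vert_vals <- matrix(vert_vals, ncol = 3)
      }
    }
    for (i in seq_len(nr)) {
      r <- radii[i]
      # the dilated isosurface is needed for cut area and for the area
      # normalization denominator of surface/cut measures
      iso <- isosurface_mesh(vals, sp, r)
      iso_areas <- triangle_areas(iso)
      shell_area[i] <- sum(iso_areas)
      clipped <- box_face_area_below(vals, sp, r)
      truncation[i] <- if (shell_area[i] + clipped > 0)
        clipped / (shell_area[i] + clipped) else 0
      if ("cut_area" %in% measures) {
        cut_area[i] <- if (empty_observed || nrow(iso) == 0) 0 else
          sum(iso_areas[points_in_mask(observed_mask, sp,
                                       triangle_centroids(iso))])
      }
      if ("surface" %in% measures) {
        surface[i] <- if (empty_observed || nrow(obs_mesh) == 0) 0 else
          sum(obs_areas[cent_vals <= r])
      }
      if ("contour" %in% measures) {
        contour[i] <- if (empty_observed || nrow(obs_mesh) == 0) 0 else
          mesh_isoline_length(obs_mesh, vert_vals, r)
      }
    }
    max_trunc <- max(truncation, na.rm = TRUE)
    if (max_trunc > 0.10)
      warnf("dilated surface truncated by the box (up to %.1f%% of its area); enlarge box_margin or reduce radii",
            100 * max_trunc)
  }
  if (!"volume" %in% measures) volume <- rep(NA_real_, nr)

  out <- data.frame(radius = radii, volume = volume, surface = surface,
                    cut_area = cut_area, contour = contour,
                    shell_volume = shell_volume, shell_area = shell_area,
                    truncation = truncation)
  attr(out, "roi_id") <- roi_id
  attr(out, "observed_label") <- observed_label
  attr(out, "total_observed_volume") <- sum(observed_mask) * voxvol
  attr(out, "ref_volume") <- field$ref_volume
  class(out) <- c("MeasureCurve", "data.frame")
  out
}

#' Normalize relational curves by spherical growth
#'
#' Cumulative measures inflate with the dilation radius simply because the
#' dilated domain grows; normalization converts them to proportional
#' coverage. Volume is divided by the volume of the dilated shell
#' `Y^r \ Y`; surface and cut area by the area of the dilated surface
#' `dY^r` (both computed on the same grid, so truncation cancels); contour
#' by the circumference `2 pi (r_eq + r)` of the reference's
#' volume-equivalent sphere grown by r. Radii with zero denominator yield
#' `NA`.
#'
#' @param curve A `MeasureCurve` from [relational_curves()].
#' @return The curve with `norm_volume`, `norm_surface`, `norm_cut_area`,
#'   `norm_contour` columns added (where the raw measure was computed).
#' @export
normalize_curves <- function(curve) {
  stopifnot(inherits(curve, "MeasureCurve"))
  r_eq <- (3 * attr(curve, "ref_volume") / (4 * pi))^(1 / 3)
  safe_div <- function(num, den) ifelse(is.na(num) | den <= 0, NA_real_,
                                        num / den)
  curve$norm_volume <- safe_div(curve$volume, curve$shell_volume)
  curve$norm_surface <- safe_div(curve$surface, curve$shell_area)
  curve$norm_cut_area <- safe_div(curve$cut_area, curve$shell_area)
  curve$norm_contour <- safe_div(curve$contour,
                                 2 * pi * (r_eq + curve$radius))
  curve
}

#' Restrict a measure curve to a radius window
#'
#' The default window spans 25 to 175 nm from the PSD, the perisynaptic
#' interval over which astrocytic engagement is functionally most relevant.
#'
#' @param curve A `MeasureCurve`.
#' @param lo,hi Window bounds in nm; must lie within the computed radii
#'   span.
#' @return The curve restricted to radii in `[lo, hi]`.
#' @export
restrict_window <- function(curve, lo = 25, hi = 175) {
  stopifnot(inherits(curve, "MeasureCurve"))
  if (lo > hi) stopf("window lower bound exceeds upper bound")
  if (lo < min(curve$radius) || hi > max(curve$radius))
    stopf("window [%g, %g] nm outside computed radii span [%g, %g] nm",
          lo, hi, min(curve$radius), max(curve$radius))
  out <- curve[curve$radius >= lo & curve$radius <= hi, , drop = FALSE]
  for (a in c("roi_id", "observed_label", "total_observed_volume",
              "ref_volume"))
    attr(out, a) <- attr(curve, a)
  class(out) <- class(curve)
  out
}
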