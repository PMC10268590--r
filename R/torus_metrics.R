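# Boundary voxels of a mask: mask voxels with at least one face-neighbor
# outside the mask (6-connectivity; outside the array counts as outside).
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  # neighbor along each axis, both directions; FALSE padding at the faces
  shift_and <- function(interior, axis, dir) {
    nb <- array(FALSE, dim = d)
    n <- d[axis]
    if (n < 2) return(interior & FALSE)
    src <- if (dir > 0) 2:n else 1:(n - 1)
    dst <- if (dir > 0) 1:(n - 1) else 2:n
    if (axis == 1) nb[dst, , ] <- mask[src, , ]
    if (axis == 2) nb[, dst, ] <- mask[, src, ]
    if (axis == 3) nb[, , dst] <- mask[, , src]
    interior & nb
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, axis, dir)
  mask & !interior
}

# Anisotropic Euclidean distance (nm) from every voxel center to the
# nearest TRUE voxel center of `mask`.
distance_to_mask <- function(mask, spacing) {
  d <- dim(mask)
  vals <- edt_sq_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(vals), dim = d)
}

#' Minimum edge-to-edge distance from the PSD to the astrocyte
#'
#' The minimum, over PSD boundary voxels, of the anisotropic Euclidean
#' distance to the nearest astrocyte boundary voxel (distances between
#' boundary voxel centers). When a torus region is supplied the astrocyte
#' mask is restricted to it before the search, so the measurement honors
#' the predefined analytic domain. Returns `Inf` when no astrocyte voxel
#' lies in the search domain.
#'
#' @param psd_mask Logical 3D array, non-empty.
#' @param astro_mask Logical 3D array of astrocyte voxels.
#' @param spacing Per-axis nm (z, y, x).
#' @param region Optional `TorusRegion` restricting the astrocyte.
#' @return Distance in nm, or `Inf`.
#' @export
min_distance_psd_to_astrocyte <- function(psd_mask, astro_mask, spacing,
                                          region = NULL) {
  if (!any(psd_mask)) stopf("PSD mask is empty")
  if (!is.null(region)) {
    stopifnot(inherits(region, "TorusRegion"))
    astro_mask <- astro_mask & region$mask
  }
  if (!any(astro_mask)) return(Inf)
  astro_b <- boundary_voxels(astro_mask)
  psd_b <- boundary_voxels(psd_mask)
  dfield <- distance_to_mask(astro_b, spacing)
  min(dfield[psd_b])
}

#' Astrocyte volume inside the torus region
#'
#' @param astro_mask Logical 3D array of astrocyte voxels.
#' @param region A `TorusRegion`.
#' @param spacing Per-axis nm (z, y, x).
#' @return Volume in nm^3 (voxel count times voxel volume).
#' @export
astro_volume_in_torus <- function(astro_mask, region, spacing) {
  stopifnot(inherits(region, "TorusRegion"))
  sum(astro_mask & region$mask) * prod(spacing)
}

#' Compute the per-ROI torus scalar metrics
#'
#' For one ROI: PSD volume, minimum PSD-to-astrocyte distance within the
#' torus, and astrocyte volume within the torus (the coverage proxy within
#' radius `outer_factor * r_max` of the PSD).
#'
#' @param roi A `SynapseROI`.
#' @param depth Torus depth, nm.
#' @param inner_factor,outer_factor Torus radial bounds as multiples of
#'   `r_max`.
#' @return One-row data frame: roi_id, group, spine_class, psd_volume,
#'   min_distance, astro_volume, torus_truncated_fraction.
#' @export
compute_torus_metrics <- function(roi, depth = 300, inner_factor = 0.75,
                                  outer_factor = 1.5) {
  stopifnot(inherits(roi, "SynapseROI"))
  vol <- roi$volume
  psd <- label_mask(vol, "psd")
  astro <- label_mask(vol, "astrocyte")
  frame <- fit_psd_frame(psd, vol$spacing, astro_mask = astro)
  region <- build_torus_region(frame, vol, depth = depth,
                               inner_factor = inner_factor,
                               outer_factor = outer_factor)
  data.frame(
    roi_id = roi$roi_id, group = roi$group, spine_class = roi$spine_class,
    psd_volume = frame$psd_volume,
    min_distance = min_distance_psd_to_astrocyte(psd, astro, vol$spacing,
                                                 region = region),
    astro_volume = astro_volume_in_torus(astro, region, vol$spacing),
    torus_truncated_fraction = region$truncated_fraction,
    stringsAsFactors = FALSE)
}

#' Partition ROIs by the astrocytic-apposition inclusion filter
#'
#' ROIs without astrocytic apposition within `threshold` nm of the PSD
#' (minimum distance, inclusive) are excluded from analysis, mirroring the
#' screening of segmented synapses for perisynaptic astrocyte presence.
#'
#' @param rois List of `SynapseROI`.
#' @param metrics Data frame from [compute_torus_metrics()] rows, one per
#'   ROI (matched by roi_id); must contain `min_distance`.
#' @param threshold Inclusion threshold in nm (<=, inclusive).
#' @return List with `included` and `excluded` ROI lists, the annotated
#'   `metrics` table (logical `included`, character `exclusion_reason`),
#'   and `counts`.
#' @export
filter_rois <- function(rois, metrics, threshold = 100) {
  stopifnot(is.data.frame(metrics), "min_distance" %in% names(metrics))
  ids <- vapply(rois, function(r) r$roi_id, character(1))
  if (!all(ids %in% metrics$roi_id))
    stopf("metrics rows missing for ROIs: %s",
          paste(setdiff(ids, metrics$roi_id), collapse = ", "))
  md <- metrics$min_distance[match(ids, metrics$roi_id)]
  keep <- is.finite(md) & md <= threshold
  metrics$included <- metrics$min_distance <= threshold &
    is.finite(metrics$min_distance)
  metrics$exclusion_reason <- ifelse(
    metrics$included, "",
    sprintf("no astrocytic apposition within %.0f nm (min distance %s nm)",
            threshold, format(round(metrics$min_distance, 1))))
  rois <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]; r$included <- keep[i]; r
  })
  list(included = rois[keep], excluded = rois[!keep], metrics = metrics,
       counts = c(loaded = length(rois), included = sum(keep),
                  excluded = sum(!keep)))
}

#' Scalar group summary (mean and SEM per group)
#'
#' @param metrics Annotated metrics table.
#' @param columns Metric columns to summarize.
#' @return Long data frame: group, metric, n, mean, sem.
#' @export
summarize_torus_metrics <- function(metrics,
                                    columns = c("psd_volume", "min_distance",
                                                "astro_volume")) {
  out <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    for (cl in columns) {
      v <- sub[[cl]]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = cl, n = length(v), mean = mean(v),
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
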