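# Extract one measure column (raw or normalized) from a list of
# MeasureCurve objects as an n_curves x n_radii matrix; validates that all
# curves share the radii grid.
curves_matrix <- function(curves, measure = "volume", normalized = TRUE,
                          window = NULL) {
  if (length(curves) == 0) stopf("no curves supplied")
  col <- if (normalized) paste0("norm_", measure) else measure
  radii <- curves[[1]]$radius
  for (cu in curves) {
    if (!identical(cu$radius, radii))
      stopf("curves have mismatched radii grids")
    if (!col %in% names(cu))
      stopf("curves lack column '%s' (was the measure computed/normalized?)",
            col)
  }
  M <- t(vapply(curves, function(cu) cu[[col]], numeric(length(radii))))
  if (!is.null(window)) {
    keep <- radii >= window[1] & radii <= window[2]
    if (!any(keep)) stopf("window [%g, %g] contains no radii", window[1],
                          window[2])
    M <- M[, keep, drop = FALSE]
    radii <- radii[keep]
  }
  if (anyNA(M)) stopf("curves contain NA values for measure '%s'", col)
  list(M = M, radii = radii)
}

#' Absolute-AUC distance between two groups of measurement curves
#'
#' The distance t' between group mean curves is the trapezoidal integral,
#' over the radius window, of the absolute difference of the means
#' (the area between the mean curves). The alternative reading -- the
#' absolute value of the integral of the signed difference -- is available
#' via `mode = "net"`.
#'
#' @param groupA,groupB Lists of `MeasureCurve` sharing one radii grid.
#' @param window Radius window `c(lo, hi)` in nm.
#' @param measure One of "volume", "surface", "cut_area", "contour".
#' @param normalized Use the normalized curves?
#' @param mode `"abs"` integrates `|meanA - meanB|`; `"net"` takes
#'   `|integral(meanA - meanB)|`.
#' @return Distance t' in measure-units x nm.
#' @export
curve_auc_distance <- function(groupA, groupB, window = c(25, 175),
                               measure = "volume", normalized = TRUE,
                               mode = c("abs", "net")) {
  mode <- match.arg(mode)
  a <- curves_matrix(groupA, measure, normalized, window)
  b <- curves_matrix(groupB, measure, normalized, window)
  if (!identical(a$radii, b$radii))
    stopf("groups have mismatched radii grids")
  d <- colMeans(a$M) - colMeans(b$M)
  if (mode == "abs") trapz(a$radii, abs(d)) else abs(trapz(a$radii, d))
}

#' Monte Carlo permutation test on the absolute-AUC curve distance
#'
#' Pools the curves of both groups and re-splits them uniformly at random
#' into groups of the original sizes, without replacement, `n_perm` times;
#' the null distances t_1..t_n are compared with the observed t' by
#' one-sided exceedance, p = (1 + #\{t_i >= t'\}) / (n_perm + 1), so p is
#' always positive and exact under exchangeability.
#'
#' @inheritParams curve_auc_distance
#' @param n_perm Number of permutations (>= 100 for useful resolution).
#' @param seed Integer seed; results are fully determined by (inputs, seed).
#' @return An object of class `PermutationResult`: observed distance t',
#'   null distances, p value, the signed net area (meanA - meanB,
#'   integrated; its sign gives the direction of the effect), group sizes,
#'   seed, window, measure, normalized flag.
#' @export
permutation_test <- function(groupA, groupB, n_perm = 10000, seed = 1L,
                             window = c(25, 175), measure = "volume",
                             normalized = TRUE, mode = c("abs", "net")) {
  mode <- match.arg(mode)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stopf("each group needs >= 2 curves")
  if (n_perm < 100)
    warnf("n_perm = %d gives coarse p-value resolution; use >= 100", n_perm)
  a <- curves_matrix(groupA, measure, normalized, window)
  b <- curves_matrix(groupB, measure, normalized, window)
  if (!identical(a$radii, b$radii))
    stopf("groups have mismatched radii grids")
  radii <- a$radii
  pool <- rbind(a$M, b$M)
  n <- nA + nB

  dist_stat <- function(mA, mB) {
    d <- mA - mB
    if (mode == "abs") trapz(radii, abs(d)) else abs(trapz(radii, d))
  }
  mA <- colMeans(pool[seq_len(nA), , drop = FALSE])
  mB <- colMeans(pool[nA + seq_len(nB), , drop = FALSE])
  observed <- dist_stat(mA, mB)
  signed_area <- trapz(radii, mA - mB)

  null_distances <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, nA)
      dist_stat(colMeans(pool[idx, , drop = FALSE]),
                colMeans(pool[-idx, , drop = FALSE]))
    }, numeric(1))
  })
  p <- (1 + sum(null_distances >= observed)) / (n_perm + 1)

  structure(list(observed_distance = observed,
                 null_distances = null_distances, n_perm = n_perm,
                 p_value = p, signed_area = signed_area,
                 direction = sign(signed_area),
                 group_sizes = c(A = nA, B = nB), seed = seed,
                 window = window, measure = measure,
                 normalized = normalized, mode = mode),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(paste0("Permutation test (%s%s, window %g-%g nm): t' = %.4g, ",
                     "p = %.4g (n_perm = %d, seed %d)\n"),
              if (x$normalized) "normalized " else "", x$measure,
              x$window[1], x$window[2], x$observed_distance, x$p_value,
              x$n_perm, x$seed))
  invisible(x)
}

#' Scalar two-group comparison: F test of variances, Welch t test
#'
#' Always reports the unequal-variance (Welch) two-tailed t test; the F
#' test of variance equality annotates the comparison but never switches
#' the t variant.
#'
#' @param groupA,groupB Numeric vectors (>= 2 finite values each).
#' @return List with the F ratio and p value, Welch t statistic, df and p
#'   value, and group means/sds/sizes.
#' @export
scalar_tests <- function(groupA, groupB) {
  a <- groupA[is.finite(groupA)]
  b <- groupB[is.finite(groupB)]
  if (length(a) < 2 || length(b) < 2)
    stopf("each group needs >= 2 finite values")
  if (sd(a) == 0 && sd(b) == 0)
    stopf("degenerate test: zero variance in both groups")
  ft <- var.test(a, b)
  tt <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(f_ratio = unname(ft$statistic), f_p = ft$p.value,
       t_statistic = unname(tt$statistic), t_df = unname(tt$parameter),
       t_p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
       n_a = length(a), n_b = length(b))
}

#' Validate spine classes by relational curves of the spine itself
#'
#' Re-runs the relational measures with the dendritic spine (not the
#' astrocyte) as the observed object, then compares spine classes
#' (thin vs mushroom, pooled across groups; expected to differ) and groups
#' within each spine class (expected similar when classes are balanced
#' across groups). Classes with fewer than 2 ROIs are skipped with a
#' warning.
#'
#' @param rois List of `SynapseROI` with spine_class labels.
#' @param radii Dilation radii (nm) for the spine curves.
#' @param window Comparison window, nm.
#' @param measure,normalized Curve measure compared.
#' @param n_perm,seed Permutation parameters.
#' @return List with `curves` (per ROI), `class_comparison`
#'   (thin vs mushroom `PermutationResult` or NULL), and
#'   `within_class` (per class, group-comparison results or NULL).
#' @export
classify_validation <- function(rois, radii = seq(25, 500, by = 25),
                                window = c(25, 175), measure = "volume",
                                normalized = TRUE, n_perm = 1000,
                                seed = 1L) {
  curves <- lapply(rois, function(roi) {
    vol <- roi$volume
    field <- reference_distance_field(label_mask(vol, "psd"), vol$spacing)
    cu <- relational_curves(label_mask(vol, "spine"), field, radii,
                            measures = "volume",
                            observed_label = "spine", roi_id = roi$roi_id)
    normalize_curves(cu)
  })
  classes <- vapply(rois, function(r) r$spine_class, character(1))
  groups <- vapply(rois, function(r) r$group, character(1))

  by_class <- split(seq_along(rois), classes)
  usable <- names(by_class)[vapply(by_class, length, integer(1)) >= 2]
  skipped <- setdiff(names(by_class), usable)
  if (length(skipped))
    warnf("spine classes skipped (fewer than 2 ROIs): %s",
          paste(skipped, collapse = ", "))

  class_comparison <- NULL
  if (all(c("thin", "mushroom") %in% usable)) {
    class_comparison <- permutation_test(
      curves[by_class[["thin"]]], curves[by_class[["mushroom"]]],
      n_perm = n_perm, seed = seed, window = window, measure = measure,
      normalized = normalized)
  }

  within_class <- list()
  for (cl in usable) {
    idx <- by_class[[cl]]
    gs <- split(idx, groups[idx])
    gs <- gs[vapply(gs, length, integer(1)) >= 2]
    if (length(gs) >= 2) {
      pair <- utils::combn(names(gs), 2)
      res <- list()
      for (j in seq_len(ncol(pair))) {
        g1 <- pair[1, j]; g2 <- pair[2, j]
        res[[paste(g1, g2, sep = "_vs_")]] <- permutation_test(
          curves[gs[[g1]]], curves[gs[[g2]]], n_perm = n_perm,
          seed = seed + j, window = window, measure = measure,
          normalized = normalized)
      }
      within_class[[cl]] <- res
    } else {
      within_class[cl] <- list(NULL)
    }
  }
  list(curves = curves, class_comparison = class_comparison,
       within_class = within_class, skipped = skipped)
}
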