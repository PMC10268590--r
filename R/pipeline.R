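#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. All defaults equal
#' the method's printed constants -- torus factors 0.75/1.5 with 300 nm
#' depth, dilation radii up to 1000 nm, analysis window 25-175 nm,
#' 100 nm apposition filter -- so an empty override reproduces the
#' reference parameterization.
#'
#' @param mode "simulate" (generate a synthetic cohort) or "load" (read a
#'   manifest of label volumes).
#' @param cohort A [cohort_spec()] for simulate mode; built from `seed` and
#'   defaults when NULL.
#' @param manifest For load mode: CSV path with columns roi_id, path,
#'   group, spine_class; volume spacing passed via `spacing`.
#' @param spacing Voxel spacing for loaded TIFF volumes (z, y, x), nm.
#' @param torus_depth,torus_inner,torus_outer Torus geometry.
#' @param radii_step,radii_max Dilation radii grid, nm.
#' @param window Analysis window `c(lo, hi)`, nm.
#' @param filter_threshold Apposition inclusion threshold, nm (inclusive).
#' @param measures Curve measures to compute.
#' @param normalized Compare normalized curves?
#' @param observed Observed object for the curves.
#' @param n_perm,seed Permutation count and master seed (stage seeds are
#'   derived deterministically from it).
#' @param out_dir Output directory (created); NULL for tempdir.
#' @param spine_class_validation Also run the spine-as-observed-object
#'   class validation?
#' @return Validated list of class `RunConfig`.
#' @export
run_config <- function(mode = c("simulate", "load"), cohort = NULL,
                       manifest = NULL, spacing = c(40, 7, 7),
                       torus_depth = 300, torus_inner = 0.75,
                       torus_outer = 1.5, radii_step = 25,
                       radii_max = 1000, window = c(25, 175),
                       filter_threshold = 100,
                       measures = c("volume", "surface", "cut_area",
                                    "contour"),
                       normalized = TRUE, observed = "astrocyte",
                       n_perm = 10000, seed = 1L, out_dir = NULL,
                       spine_class_validation = FALSE) {
  mode <- match.arg(mode)
  if (!(torus_inner > 0 && torus_inner < torus_outer))
    stopf("need 0 < torus_inner < torus_outer")
  if (torus_depth <= 0) stopf("torus_depth must be positive")
  if (radii_step <= 0 || radii_max < radii_step)
    stopf("invalid radii grid: step %g, max %g", radii_step, radii_max)
  radii <- seq(radii_step, radii_max, by = radii_step)
  if (window[1] > window[2] || window[1] < min(radii) ||
      window[2] > max(radii))
    stopf("window [%g, %g] nm not contained in radii span [%g, %g] nm",
          window[1], window[2], min(radii), max(radii))
  if (mode == "load" && is.null(manifest))
    stopf("load mode requires a manifest CSV")
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(mode = mode, cohort = cohort, manifest = manifest,
                 spacing = spacing, torus_depth = torus_depth,
                 torus_inner = torus_inner, torus_outer = torus_outer,
                 radii_step = radii_step, radii_max = radii_max,
                 radii = radii, window = window,
                 filter_threshold = filter_threshold, measures = measures,
                 normalized = normalized, observed = observed,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir,
                 spine_class_validation = spine_class_validation),
            class = "RunConfig")
}

# Canonical plain-text key-value rendering of a config; hashed to stamp
# outputs. The hash changes iff any parameter changes.
config_canonical_text <- function(config) {
  flat <- list(
    mode = config$mode,
    spacing = config$spacing, torus_depth = config$torus_depth,
    torus_inner = config$torus_inner, torus_outer = config$torus_outer,
    radii_step = config$radii_step, radii_max = config$radii_max,
    window = config$window, filter_threshold = config$filter_threshold,
    measures = config$measures, normalized = config$normalized,
    observed = config$observed, n_perm = config$n_perm, seed = config$seed,
    spine_class_validation = config$spine_class_validation,
    manifest = if (is.null(config$manifest)) "" else config$manifest,
    cohort = if (is.null(config$cohort)) "" else {
      s <- config$cohort
      paste(s$n_per_group, paste(names(s$groups), collapse = ","),
            paste(unlist(s$groups), collapse = ","),
            paste(unlist(s$base_params[
              !vapply(s$base_params, is.null, logical(1))]), collapse = ","),
            s$class_threshold, s$seed)
    })
  keys <- sort(names(flat))
  paste(vapply(keys, function(k)
    sprintf("%s = %s", k, paste(format(flat[[k]], digits = 15),
                                collapse = " ")), character(1)),
    collapse = "\n")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical key-value rendering; stamped into every output so
#' results are traceable to their exact parameterization.
#'
#' @param config A `RunConfig`.
#' @return Hex MD5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(config_canonical_text(config), tf)
  unname(tools::md5sum(tf))
}

# Read ROIs for load mode.
load_rois_from_manifest <- function(manifest, spacing) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("roi_id", "path", "group", "spine_class")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stopf("manifest missing columns: %s", paste(miss, collapse = ", "))
  base <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    vol <- read_label_volume(p, spacing = spacing)
    synapse_roi(vol, roi_id = man$roi_id[i], group = man$group[i],
                spine_class = man$spine_class[i],
                groups = unique(man$group))
  })
}

run_stage <- function(stage, roi_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed%s: %s", stage,
          if (is.null(roi_id)) "" else sprintf(" at ROI '%s'", roi_id),
          conditionMessage(e))
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates or loads ROIs, computes torus scalar metrics, applies the
#' apposition filter, computes and normalizes relational curves for the
#' included ROIs, runs group comparisons (permutation tests per measure,
#' Welch/F tests for the scalars), and writes CSV/JSON outputs stamped
#' with the configuration hash and seed. Re-running with an identical
#' configuration reproduces every output byte-for-byte.
#'
#' @param config A `RunConfig`.
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, the run report: config, hash, counts, metrics table,
#'   curves, comparison results, output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(config)
  out_dir <- if (is.null(config$out_dir)) tempfile("perisyn_run_")
             else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say("run %s: output to %s", hash, out_dir)

  # stage 1: ROIs
  rois <- run_stage("input", NULL, {
    if (config$mode == "simulate") {
      cohort <- config$cohort
      if (is.null(cohort)) cohort <- cohort_spec(seed = config$seed)
      generate_cohort(cohort)
    } else {
      load_rois_from_manifest(config$manifest, config$spacing)
    }
  })
  say("stage input: %d ROIs", length(rois))

  # stage 2: torus metrics
  metrics <- do.call(rbind, lapply(rois, function(roi)
    run_stage("torus_metrics", roi$roi_id,
              compute_torus_metrics(roi, depth = config$torus_depth,
                                    inner_factor = config$torus_inner,
                                    outer_factor = config$torus_outer))))
  say("stage torus_metrics: %d rows", nrow(metrics))

  # stage 3: apposition filter
  flt <- run_stage("filter", NULL,
                   filter_rois(rois, metrics,
                               threshold = config$filter_threshold))
  metrics <- flt$metrics
  say("stage filter: %d included, %d excluded of %d",
      flt$counts[["included"]], flt$counts[["excluded"]],
      flt$counts[["loaded"]])
  if (length(flt$included) == 0)
    stopf(paste0("no ROI passed the %.0f nm apposition filter: ",
                 "empty analysis set, pipeline halted"),
          config$filter_threshold)

  # stage 4: relational curves
  curves <- lapply(flt$included, function(roi) {
    run_stage("relational_curves", roi$roi_id, {
      vol <- roi$volume
      field <- reference_distance_field(label_mask(vol, "psd"),
                                        vol$spacing)
      cu <- relational_curves(label_mask(vol, config$observed), field,
                              config$radii, measures = config$measures,
                              observed_label = config$observed,
                              roi_id = roi$roi_id)
      normalize_curves(cu)
    })
  })
  say("stage relational_curves: %d curves x %d radii", length(curves),
      length(config$radii))

  # stage 5: group comparisons
  groups <- vapply(flt$included, function(r) r$group, character(1))
  comparisons <- list()
  scalar_results <- list()
  gnames <- unique(groups)
  if (length(gnames) >= 2) {
    pairs <- utils::combn(gnames, 2)
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      key <- paste(g1, g2, sep = "_vs_")
      for (m in config$measures) {
        comparisons[[paste(key, m, sep = ".")]] <- run_stage(
          "permutation_test", NULL,
          permutation_test(curves[groups == g1], curves[groups == g2],
                           n_perm = config$n_perm,
                           seed = config$seed + 101L * j,
                           window = config$window, measure = m,
                           normalized = config$normalized))
      }
      for (sc in c("psd_volume", "min_distance", "astro_volume")) {
        va <- metrics[[sc]][metrics$included & metrics$group == g1]
        vb <- metrics[[sc]][metrics$included & metrics$group == g2]
        scalar_results[[paste(key, sc, sep = ".")]] <- run_stage(
          "scalar_tests", NULL, scalar_tests(va, vb))
      }
    }
  }
  say("stage group_stats: %d curve comparisons, %d scalar comparisons",
      length(comparisons), length(scalar_results))

  class_validation <- NULL
  if (isTRUE(config$spine_class_validation)) {
    class_validation <- run_stage("classify_validation", NULL,
      classify_validation(flt$included,
                          radii = config$radii[config$radii <=
                                                 config$window[2] + 100],
                          window = config$window,
                          normalized = config$normalized,
                          n_perm = config$n_perm,
                          seed = config$seed + 9001L))
  }

  # stage 6: outputs
  metrics_path <- file.path(out_dir, "torus_metrics.csv")
  scalar_records <- do.call(rbind, lapply(
    c("psd_volume", "min_distance", "astro_volume"), function(m)
      data.frame(roi_id = metrics$roi_id, group = metrics$group,
                 spine_class = metrics$spine_class, metric = m,
                 radius = NA_real_, value = metrics[[m]],
                 units = c(psd_volume = "nm^3", min_distance = "nm",
                           astro_volume = "nm^3")[[m]],
                 included = metrics$included,
                 config_hash = hash, stringsAsFactors = FALSE)))
  write_results_table(scalar_records, metrics_path,
                      config = list(hash = hash), seed = config$seed)

  curve_rows <- list()
  for (cu in curves) {
    for (m in config$measures) {
      curve_rows[[length(curve_rows) + 1L]] <- data.frame(
        roi_id = attr(cu, "roi_id"), observed = attr(cu, "observed_label"),
        radius = cu$radius, measure = m, raw = cu[[m]],
        normalized = cu[[paste0("norm_", m)]],
        config_hash = hash, stringsAsFactors = FALSE)
    }
  }
  curves_path <- file.path(out_dir, "relational_curves.csv")
  write.csv(do.call(rbind, curve_rows), curves_path, row.names = FALSE)

  stats_path <- file.path(out_dir, "group_comparisons.json")
  jsonlite::write_json(list(
    config_hash = hash, seed = config$seed,
    counts = as.list(flt$counts),
    group_summary = summarize_torus_metrics(
      metrics[metrics$included, , drop = FALSE]),
    curve_comparisons = lapply(comparisons, function(x)
      list(measure = x$measure, normalized = x$normalized,
           observed_distance = x$observed_distance, p_value = x$p_value,
           direction = x$direction, n_perm = x$n_perm, seed = x$seed,
           window = x$window, group_sizes = as.list(x$group_sizes))),
    scalar_comparisons = scalar_results),
    stats_path, auto_unbox = TRUE, digits = NA, null = "null")

  say("run complete in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(list(config = config, hash = hash, out_dir = out_dir,
                 counts = flt$counts, metrics = metrics, curves = curves,
                 comparisons = comparisons,
                 scalar_comparisons = scalar_results,
                 class_validation = class_validation,
                 paths = c(metrics = metrics_path, curves = curves_path,
                           stats = stats_path)))
}

#' Plot group mean curves with pointwise bootstrap bands
#'
#' Mean curve per group with pointwise 95 percent percentile-bootstrap
#' bands over ROIs (a labeled convention of this package).
#'
#' @param curves List of `MeasureCurve`.
#' @param groups Character vector of group labels, one per curve.
#' @param measure,normalized Which column to plot.
#' @param window Optional radius window to restrict the plot.
#' @param n_boot Bootstrap replicates for the bands.
#' @param seed Seed for the bootstrap.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the per-group summary (mean, lo, hi per radius).
#' @export
plot_group_curves <- function(curves, groups, measure = "volume",
                              normalized = TRUE, window = NULL,
                              n_boot = 1000, seed = 1L, ...) {
  cm <- curves_matrix(curves, measure, normalized, window)
  gnames <- unique(groups)
  cols <- seq_along(gnames) + 1
  summ <- list()
  for (gi in seq_along(gnames)) {
    M <- cm$M[groups == gnames[gi], , drop = FALSE]
    bands <- with_preserved_seed(seed + gi, {
      reps <- replicate(n_boot,
                        colMeans(M[sample.int(nrow(M), replace = TRUE), ,
                                   drop = FALSE]))
      apply(reps, 1, quantile, probs = c(0.025, 0.975))
    })
    summ[[gnames[gi]]] <- list(radii = cm$radii, mean = colMeans(M),
                               lo = bands[1, ], hi = bands[2, ])
  }
  ylim <- range(unlist(lapply(summ, function(s) c(s$lo, s$hi))))
  graphics::matplot(cm$radii, sapply(summ, `[[`, "mean"), type = "l",
                    lty = 1, lwd = 2, col = cols,
                    xlab = "distance from PSD (nm)",
                    ylab = paste0(if (normalized) "normalized " else "",
                                  measure), ylim = ylim, ...)
  for (gi in seq_along(gnames)) {
    s <- summ[[gnames[gi]]]
    graphics::polygon(c(s$radii, rev(s$radii)), c(s$lo, rev(s$hi)),
                      col = grDevices::adjustcolor(cols[gi], 0.2),
                      border = NA)
  }
  graphics::legend("topleft", legend = gnames, col = cols, lty = 1,
                   lwd = 2, bty = "n")
  invisible(summ)
}
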