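#' Default label table for tripartite-synapse segmentations
#'
#' One integer label per structure: dendritic spine, postsynaptic density,
#' astrocytic process, axon terminal. Multiple fragments of one structure
#' share one label (they form a single observed object).
#'
#' @return Named integer vector.
#' @export
default_label_map <- function() {
  c(spine = 1L, psd = 2L, astrocyte = 3L, axon = 4L)
}

#' Construct a labeled segmentation volume
#'
#' A `LabeledVolume` is the universal input of the pipeline: a 3D grid of
#' non-negative integer labels (0 = background) in (z, y, x) axis order,
#' together with per-axis voxel spacing in nm and a name-to-label table.
#'
#' @param labels 3D integer array, axis order (z, y, x).
#' @param spacing Numeric length-3, voxel edge lengths in nm (z, y, x);
#'   all strictly positive.
#' @param label_map Named integer vector mapping structure names to label
#'   values; must cover at least spine, psd, astrocyte and axon.
#' @return An object of class `LabeledVolume` with fields `labels`,
#'   `spacing`, `label_map`.
#' @export
labeled_volume <- function(labels, spacing, label_map = default_label_map()) {
  if (length(dim(labels)) != 3L)
    stopf("labels must be a 3D array, got %d dims", length(dim(labels)))
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stopf("labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stopf("labels must be an integer array")
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stopf("spacing must be 3 strictly positive nm values (z, y, x)")
  required <- c("spine", "psd", "astrocyte", "axon")
  if (is.null(names(label_map)) || !all(required %in% names(label_map)))
    stopf("label_map must name at least: %s", paste(required, collapse = ", "))
  label_map <- vapply(label_map, as.integer, integer(1))
  present <- sort(unique(as.vector(labels)))
  unknown <- setdiff(present, c(0L, unname(label_map)))
  if (length(unknown))
    stopf("labels contain values not in label_map: %s",
          paste(unknown, collapse = ", "))
  spacing <- as.numeric(spacing)
  names(spacing) <- c("z", "y", "x")
  structure(list(labels = labels, spacing = spacing, label_map = label_map),
            class = "LabeledVolume")
}

#' @export
print.LabeledVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("LabeledVolume %d x %d x %d voxels (z,y,x), spacing %s nm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  counts <- vapply(names(x$label_map),
                   function(nm) sum(x$labels == x$label_map[[nm]]), numeric(1))
  cat("  voxels per label:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the voxel mask of one labeled structure
#'
#' @param volume A `LabeledVolume`.
#' @param name Structure name present in the volume's label map.
#' @return Logical 3D array of the same dimensions.
#' @export
label_mask <- function(volume, name) {
  stopifnot(inherits(volume, "LabeledVolume"))
  if (!name %in% names(volume$label_map))
    stopf("unknown label name '%s'", name)
  volume$labels == volume$label_map[[name]]
}

#' @rdname label_mask
#' @export
voxel_volume_nm3 <- function(volume) {
  if (inherits(volume, "LabeledVolume")) prod(volume$spacing)
  else prod(volume)
}

#' Read a labeled volume from a multi-page TIFF or NRRD file
#'
#' Axis order is documented as (z, y, x) with z the cutting axis: TIFF pages
#' are z-slices. For NRRD, spacing embedded in the header is honored when
#' the `spacing` argument is omitted.
#'
#' @param path Path to a `.tif`/`.tiff` or `.nrrd` file of integer type.
#' @param spacing Per-axis nm (z, y, x). Required for TIFF; optional for
#'   NRRD (header used when omitted).
#' @param label_map Name-to-label table, see [labeled_volume()].
#' @return A `LabeledVolume`.
#' @export
read_label_volume <- function(path, spacing = NULL,
                              label_map = default_label_map()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing))
      stopf("spacing must be given for TIFF input (not stored in the file)")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (!all(vapply(pages, is.integer, logical(1))))
      stopf("TIFF pixel type is not integer; label volumes must be integer")
    d <- dim(pages[[1]])
    arr <- array(0L, dim = c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    labeled_volume(arr, spacing, label_map)
  } else if (ext == "nrrd") {
    nr <- read_nrrd(path)
    sp <- if (is.null(spacing)) nr$spacing else spacing
    if (is.null(sp))
      stopf("spacing missing: neither argument nor NRRD header provides it")
    labeled_volume(nr$data, sp, label_map)
  } else {
    stopf("unsupported extension '%s' (use .tif/.tiff or .nrrd)", ext)
  }
}

#' Write a labeled volume to a multi-page TIFF or NRRD file
#'
#' The writer round-trips bit-exactly with [read_label_volume()] for integer
#' labels. NRRD output embeds the voxel spacing in the header.
#'
#' @param volume A `LabeledVolume`.
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "LabeledVolume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    mx <- max(volume$labels)
    if (mx > 65535L) stopf("labels exceed 16-bit TIFF range")
    nz <- dim(volume$labels)[1]
    pages <- lapply(seq_len(nz), function(i) volume$labels[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else if (ext == "nrrd") {
    write_nrrd(volume$labels, path, spacing = volume$spacing)
  } else {
    stopf("unsupported extension '%s' (use .tif/.tiff or .nrrd)", ext)
  }
  invisible(path)
}

#' Construct a single-synapse region of interest
#'
#' Bundles one synapse's labeled volume with its identifier, experimental
#' group and spine class. The observed object (astrocyte or spine) and the
#' reference object (PSD) are selected from the volume by label name.
#'
#' @param volume A `LabeledVolume` whose PSD mask is non-empty.
#' @param roi_id Identifier string.
#' @param group Group label, e.g. "WT" or "R6/2".
#' @param spine_class One of "thin", "mushroom", "unclassified".
#' @param ground_truth Optional list of generator ground truth.
#' @param groups Vocabulary of admissible group labels.
#' @return An object of class `SynapseROI`.
#' @export
synapse_roi <- function(volume, roi_id, group = "WT",
                        spine_class = "unclassified",
                        ground_truth = NULL,
                        groups = c("WT", "R6/2")) {
  stopifnot(inherits(volume, "LabeledVolume"))
  if (!group %in% groups)
    stopf("group '%s' not in declared vocabulary: %s", group,
          paste(groups, collapse = ", "))
  if (!spine_class %in% c("thin", "mushroom", "unclassified"))
    stopf("spine_class must be thin, mushroom or unclassified")
  if (!any(label_mask(volume, "psd")))
    stopf("ROI '%s' has an empty PSD mask", roi_id)
  structure(list(volume = volume, roi_id = as.character(roi_id),
                 group = group, spine_class = spine_class,
                 included = NA, ground_truth = ground_truth),
            class = "SynapseROI")
}

#' @export
print.SynapseROI <- function(x, ...) {
  cat(sprintf("SynapseROI '%s' (group %s, spine class %s, included: %s)\n",
              x$roi_id, x$group, x$spine_class, format(x$included)))
  print(x$volume)
  invisible(x)
}

#' Write a measurement record table as CSV plus a JSON run summary
#'
#' Records share the schema (roi_id, group, spine_class, metric, radius,
#' value, units); `radius` is NA for scalar metrics. A JSON sidecar carries
#' the run configuration, seed and software version.
#'
#' @param records Data frame of records, or list of same-schema rows.
#' @param path Destination CSV path; the JSON summary is written alongside
#'   with extension `.json`.
#' @param config Optional named list recorded in the JSON summary.
#' @param seed Optional seed recorded in the JSON summary.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, config = list(), seed = NULL) {
  schema <- c("roi_id", "group", "spine_class", "metric", "radius",
              "value", "units")
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(schema)), schema))
    } else {
      keys <- lapply(records, function(r) sort(names(r)))
      if (!all(vapply(keys, identical, logical(1), keys[[1]])))
        stopf("records have heterogeneous schemas")
      df <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
    }
  } else {
    stopf("records must be a data frame or a list of records")
  }
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols))
    stopf("records missing columns: %s", paste(missing_cols, collapse = ", "))
  df <- df[, c(schema, setdiff(names(df), schema)), drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  summary_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(config = config, seed = seed,
         software = list(package = "perisyn",
                         version = as.character(utils::packageVersion("perisyn"))),
         n_records = nrow(df)),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
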