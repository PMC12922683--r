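#' Cell-detection parameters for the multiplex pipeline
#'
#' Defaults follow the published positive-cell-detection settings: pixel
#' resolution 0.5 um, background radius 8 um with opening by
#' reconstruction, median filter radius 1.5 um, Gaussian sigma 1.6 um,
#' nucleus area 10--100 um^2, intensity threshold 1.0 AU, shape-based
#' watershed splitting, boundary smoothing, and a 2 um nucleus expansion.
#'
#' @param pixel_resolution_um,background_radius_um,median_radius_um,gaussian_sigma_um
#'   lengths in micrometres.
#' @param opening_by_reconstruction estimate background by morphological
#'   opening by reconstruction (disc of `background_radius_um`) and
#'   subtract it before thresholding.
#' @param min_area_um2,max_area_um2 inclusive nucleus-area bounds.
#' @param intensity_threshold threshold applied to the background-subtracted
#'   smoothed image.
#' @param split_by_shape split touching nuclei with a distance-transform
#'   watershed.
#' @param smooth_boundaries morphological closing+opening (1 px disc) of the
#'   thresholded mask.
#' @param expansion_um disc expansion beyond the nucleus.
#' @export
detection_params <- function(pixel_resolution_um = 0.5,
                             background_radius_um = 8,
                             opening_by_reconstruction = TRUE,
                             median_radius_um = 1.5,
                             gaussian_sigma_um = 1.6,
                             min_area_um2 = 10, max_area_um2 = 100,
                             intensity_threshold = 1.0,
                             split_by_shape = TRUE,
                             smooth_boundaries = TRUE,
                             expansion_um = 2.0) {
  stopifnot(pixel_resolution_um > 0, background_radius_um > 0,
            median_radius_um > 0, gaussian_sigma_um > 0,
            min_area_um2 > 0, max_area_um2 > 0,
            min_area_um2 < max_area_um2, expansion_um >= 0)
  structure(list(pixel_resolution_um = pixel_resolution_um,
                 background_radius_um = background_radius_um,
                 opening_by_reconstruction = isTRUE(opening_by_reconstruction),
                 median_radius_um = median_radius_um,
                 gaussian_sigma_um = gaussian_sigma_um,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 intensity_threshold = intensity_threshold,
                 split_by_shape = isTRUE(split_by_shape),
                 smooth_boundaries = isTRUE(smooth_boundaries),
                 expansion_um = expansion_um),
            class = "detection_params")
}

#' Detect individual cells (nuclei) in a smoothed, background-subtracted
#' plane
#'
#' Operator order: median filter, Gaussian smoothing, background estimation
#' by opening-by-reconstruction and subtraction, fixed intensity threshold,
#' optional boundary smoothing, optional shape-based watershed split, and an
#' inclusive area filter in um^2.  Detection is restricted to the `within`
#' mask when given (e.g. classifier-derived DAPI+ areas); an empty `within`
#' mask yields zero detections, not an error.
#'
#' @param plane image (matrix or [image_plane()]), already at the working
#'   resolution.
#' @param params a [detection_params()].
#' @param within optional logical mask restricting detection.
#' @return integer nucleus label grid with attribute `areas_um2`.
#' @export
detect_cells <- function(plane, params = detection_params(), within = NULL) {
  m <- as_plane_matrix(plane)
  ps <- pixel_size(plane) %||% params$pixel_resolution_um
  if (!is.null(within)) {
    stopifnot(is.logical(within), identical(dim(within), dim(m)))
    if (!any(within)) {
      out <- matrix(0L, nrow(m), ncol(m))
      attr(out, "areas_um2") <- numeric(0)
      return(out)
    }
  }
  f <- median_filter(m, params$median_radius_um / ps)
  f <- gaussian_blur(f, params$gaussian_sigma_um / ps)
  if (params$opening_by_reconstruction) {
    bg <- opening_by_reconstruction(f, params$background_radius_um / ps)
    f <- f - bg
  }
  fg <- f >= params$intensity_threshold
  if (!is.null(within)) fg <- fg & within
  if (params$smooth_boundaries && any(fg)) {
    b <- matrix(as.numeric(fg), nrow(fg))
    b <- grey_erode_cpp(grey_dilate_cpp(b, 1), 1)   # closing
    b <- grey_dilate_cpp(grey_erode_cpp(b, 1), 1)   # opening
    fg <- b > 0.5
    if (!is.null(within)) fg <- fg & within
  }
  labels <- if (params$split_by_shape) watershed_split(fg)
            else label_components(fg, 8)
  flt <- filter_by_area(labels,
                        params$min_area_um2 / ps^2,
                        params$max_area_um2 / ps^2)
  out <- flt$labels
  attr(out, "areas_um2") <- flt$areas_px * ps^2
  out
}

#' Detect microglia-like cells from their own marker staining
#'
#' Runs [detect_cells()] on the marker plane itself (e.g. IBA1), restricted
#' to the classifier-derived marker-positive areas.  The detection area is
#' not expanded downstream: the detected soma is the quantification area,
#' which avoids spilling into overlapping neuron somas.
#'
#' @param iba1_plane the marker image.
#' @param params a [detection_params()].
#' @param iba1_mask logical marker-positive mask from [classify_pixels()].
#' @return integer label grid with attribute `source = "IBA1"`.
#' @export
detect_cells_iba1 <- function(iba1_plane, params = detection_params(),
                              iba1_mask) {
  out <- detect_cells(iba1_plane, params, within = iba1_mask)
  attr(out, "source") <- "IBA1"
  out
}

#' Expand nucleus labels into non-overlapping discs
#'
#' Each nucleus is dilated by `expansion_um`, with contested pixels assigned
#' to the nearest nucleus (Euclidean/Voronoi partition), so expanded labels
#' never overlap and every disc contains its nucleus.  Expansion is clipped
#' at the image border and at the ROI when given.
#'
#' @param nuclei integer nucleus label grid.
#' @param expansion_um expansion width in micrometres (0 returns the input).
#' @param pixel_size_um micrometres per pixel.
#' @param roi optional [roi()] or logical mask clipping the expansion.
#' @return integer disc label grid.
#' @export
expand_to_discs <- function(nuclei, expansion_um = 2,
                            pixel_size_um = 0.5, roi = NULL) {
  stopifnot(is.matrix(nuclei), expansion_um >= 0)
  if (expansion_um == 0 || !any(nuclei > 0)) return(nuclei)
  et <- distance_transform(nuclei > 0)
  within <- et$dist * pixel_size_um <= expansion_um
  if (!is.null(roi)) within <- within & (roi_mask(roi, dim(nuclei)) |
                                           nuclei > 0)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  idx <- which(within)
  out[idx] <- nuclei[et$nearest[idx]]
  out
}

#' Measure per-disc raw intensity
#'
#' @param target target-channel image.
#' @param discs integer disc label grid.
#' @param source detection source recorded per disc (`"DAPI"` or `"IBA1"`).
#' @param subject,region identifiers recorded per disc.
#' @return data frame of disc records: `disc_id`, `subject`, `region`,
#'   `source`, `area_px`, `centroid_row`, `centroid_col`, `raw_mean_AU`.
#' @export
measure_discs <- function(target, discs, source = "DAPI",
                          subject = "S1", region = "ROI") {
  m <- as_plane_matrix(target)
  stopifnot(identical(dim(m), dim(discs)))
  idx <- which(discs > 0)
  if (length(idx) == 0)
    return(data.frame(disc_id = integer(0), subject = character(0),
                      region = character(0), source = character(0),
                      area_px = integer(0), centroid_row = integer(0),
                      centroid_col = integer(0), raw_mean_AU = numeric(0)))
  lab <- discs[idx]
  ids <- sort(unique(lab))
  n <- tabulate(lab, nbins = max(lab))[ids]
  s <- rowsum(m[idx], lab)[, 1]
  rr <- rowsum(((idx - 1) %% nrow(m)) + 1, lab)[, 1]
  cc <- rowsum(((idx - 1) %/% nrow(m)) + 1, lab)[, 1]
  data.frame(disc_id = ids, subject = subject, region = region,
             source = source, area_px = n,
             centroid_row = as.integer(round(rr / n)),
             centroid_col = as.integer(round(cc / n)),
             raw_mean_AU = s / n, stringsAsFactors = FALSE)
}

#' Classify discs by marker positivity at their centroid
#'
#' A disc is positive for a marker iff its (rounded area-)centroid pixel
#' lies in that marker's positive mask; flags are independent per marker.
#' Discs positive for more than one marker are flagged `multi_positive` and
#' excluded from single-positive summaries.
#'
#' @param records disc records from [measure_discs()].
#' @param marker_masks named list of logical marker-positive masks.
#' @return `records` with one logical column per marker, plus
#'   `multi_positive` and `marker` (the single positive marker, `NA`
#'   otherwise).  Marker names are recorded in attribute `"markers"`.
#' @export
classify_discs <- function(records, marker_masks) {
  stopifnot(is.data.frame(records), length(marker_masks) >= 1,
            !is.null(names(marker_masks)))
  flags <- matrix(FALSE, nrow(records), length(marker_masks),
                  dimnames = list(NULL, names(marker_masks)))
  for (nm in names(marker_masks)) {
    msk <- marker_masks[[nm]]
    if (nrow(records) > 0 &&
        (any(records$centroid_row < 1 | records$centroid_row > nrow(msk)) ||
         any(records$centroid_col < 1 | records$centroid_col > ncol(msk))))
      stop("disc centroid outside image")
    if (nrow(records) > 0)
      flags[, nm] <- msk[cbind(records$centroid_row, records$centroid_col)]
  }
  npos <- rowSums(flags)
  records <- cbind(records, as.data.frame(flags))
  records$multi_positive <- npos > 1
  records$marker <- ifelse(npos == 1,
                           colnames(flags)[max.col(flags, "first")],
                           NA_character_)
  attr(records, "markers") <- names(marker_masks)
  records
}

#' Subtract the diffuse-staining baseline from disc means
#'
#' The ROI is partitioned into "high" areas (containing target-positive cell
#' bodies) and "low" areas (diffuse or absent staining) by a pixel
#' classifier; the median target intensity over the low area is measured
#' per ROI and subtracted from every disc's raw mean.  Corrected means may
#' be negative (unbiased estimator); set `clip = TRUE` to floor at zero.
#'
#' @param target target-channel image.
#' @param roi [roi()] or logical mask (`NULL` = whole image).
#' @param high either a logical "high-target" mask, or a list
#'   `list(model, features)` with a trained classifier and matching feature
#'   stack, classified here.
#' @param records disc records ([measure_discs()] output).
#' @param clip clip negative corrected means at zero.
#' @return list with `low_median` and `records` (gaining
#'   `diffuse_corrected_mean_AU`).
#' @export
diffuse_correction <- function(target, roi = NULL, high, records,
                               clip = FALSE) {
  m <- as_plane_matrix(target)
  rmask <- roi_mask(roi, dim(m))
  if (is.list(high) && !is.matrix(high))
    high <- classify_pixels(high$model, high$features)$positive
  stopifnot(is.logical(high), identical(dim(high), dim(m)))
  low <- rmask & !high
  if (!any(low))
    stop("low-target area is empty: ROI cannot be diffuse-corrected")
  low_median <- stats::median(m[low])
  records$diffuse_corrected_mean_AU <- records$raw_mean_AU - low_median
  if (clip)
    records$diffuse_corrected_mean_AU <-
      pmax(records$diffuse_corrected_mean_AU, 0)
  list(low_median = low_median, records = records)
}

#' Normalize disc intensities by the ROI's DAPI-disc upper quartile
#'
#' Within each (image, region), corrected disc means are divided by the 75th
#' percentile (linear-interpolation rule) of corrected means over all
#' DAPI-derived discs in that region.  IBA1-derived discs are normalized by
#' the same DAPI-based denominator.  Requires at least four DAPI discs and a
#' strictly positive upper quartile per region.
#'
#' @param records disc records with `diffuse_corrected_mean_AU`, `source`,
#'   `region` and optionally `image` columns.
#' @return `records` with a `normalized_intensity` column; the denominators
#'   are attached as attribute `"upper_quartiles"`.
#' @export
normalize_upper_quartile <- function(records) {
  stopifnot(is.data.frame(records),
            "diffuse_corrected_mean_AU" %in% names(records))
  if (is.null(records$image)) records$image <- "img1"
  key <- interaction(records$image, records$region, drop = TRUE)
  records$normalized_intensity <- NA_real_
  uq <- numeric(0)
  for (k in levels(key)) {
    sel <- key == k
    dapi <- sel & records$source == "DAPI"
    if (sum(dapi) < 4)
      stop(sprintf("region '%s' has fewer than 4 DAPI+ discs", k))
    q3 <- stats::quantile(records$diffuse_corrected_mean_AU[dapi], 0.75,
                          names = FALSE, type = 7)
    if (q3 <= 0)
      stop(sprintf("region '%s' has non-positive upper quartile", k))
    records$normalized_intensity[sel] <-
      records$diffuse_corrected_mean_AU[sel] / q3
    uq[k] <- q3
  }
  attr(records, "upper_quartiles") <- uq
  records
}

#' Apply region-specific marker exclusion rules
#'
#' Removes discs positive for a named marker within a named region (e.g.
#' glial and vascular markers in densely packed neuronal layers, or
#' excitatory-neuron markers in white matter), and removes multi-positive
#' discs from the single-positive summary set.
#'
#' @param records classified disc records.
#' @param rules named list: region label -> character vector of markers to
#'   exclude there.  Unknown marker names are an error.
#' @param drop_multi_positive also drop discs positive for more than one
#'   marker.
#' @return list with `records` (filtered), `removed` (data frame of per-rule
#'   removal counts) and `n_multi_removed`.
#' @export
apply_exclusions <- function(records, rules = list(),
                             drop_multi_positive = TRUE) {
  markers <- attr(records, "markers")
  removed <- data.frame(region = character(0), marker = character(0),
                        n = integer(0), stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(records))
  for (rg in names(rules)) {
    for (mk in rules[[rg]]) {
      if (!mk %in% markers)
        stop(sprintf("exclusion rule names unknown marker '%s'", mk))
      hit <- records$region == rg & records[[mk]]
      removed <- rbind(removed, data.frame(region = rg, marker = mk,
                                           n = sum(hit),
                                           stringsAsFactors = FALSE))
      drop <- drop | hit
    }
  }
  n_multi <- 0L
  if (drop_multi_positive && !is.null(records$multi_positive)) {
    n_multi <- sum(records$multi_positive & !drop)
    drop <- drop | records$multi_positive
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "markers") <- markers
  list(records = out, removed = removed, n_multi_removed = n_multi)
}

#' Summarize normalized disc intensities
#'
#' One row per (subject, region, marker) over single-positive discs: mean
#' normalized intensity, number of discs, and SEM (missing for a single
#' disc).  Marker classes with no discs in a region are absent, not zero.
#'
#' @param records normalized, filtered disc records.
#' @param value column summarized (default `normalized_intensity`).
#' @return summary data frame.
#' @export
summarize_discs <- function(records, value = "normalized_intensity") {
  stopifnot(value %in% names(records))
  sel <- !is.na(records$marker)
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(subject = character(0), region = character(0),
                      marker = character(0), mean = numeric(0),
                      n = integer(0), sem = numeric(0)))
  key <- factor(paste(r$subject, r$region, r$marker, sep = "\r"))
  splits <- split(r[[value]], key)
  first <- match(levels(key), as.character(key))
  data.frame(subject = r$subject[first], region = r$region[first],
             marker = r$marker[first],
             mean = vapply(splits, mean, 0),
             n = vapply(splits, length, 0L),
             sem = vapply(splits, function(v)
               if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
               else NA_real_, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
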