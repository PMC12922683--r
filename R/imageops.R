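#' Gaussian smoothing and related raster operators
#'
#' Separable Gaussian convolution with a normalized kernel truncated at three
#' standard deviations and edge-replicating boundary, so a constant image is
#' reproduced exactly.  All radii/sigmas are in pixels; callers convert from
#' micrometres with the plane's pixel size.
#'
#' @param img numeric matrix or [image_plane()].
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma_px) {
  m <- as_plane_matrix(img)
  stopifnot(sigma_px > 0)
  if (any(!is.finite(m))) stop("image contains non-finite pixels")
  conv_sep_cpp(m, gaussian_kernel(sigma_px))
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

#' @rdname gaussian_blur
#' @param radius_px disc radius in pixels.
#' @export
median_filter <- function(img, radius_px) {
  m <- as_plane_matrix(img)
  stopifnot(radius_px > 0)
  median_filter_cpp(m, radius_px)
}

#' Morphological opening by reconstruction
#'
#' Erodes with a disc of the given radius and reconstructs under the original
#' image by grayscale geodesic dilation.  The result estimates the smooth
#' background below objects smaller than the disc; subtracting it flattens
#' uneven illumination without clipping object tops.
#'
#' @inheritParams gaussian_blur
#' @param radius_px structuring-disc radius in pixels.
#' @export
opening_by_reconstruction <- function(img, radius_px) {
  m <- as_plane_matrix(img)
  reconstruct_dilate_cpp(grey_erode_cpp(m, radius_px), m)
}

#' Connected-component labelling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix; background 0, components labelled 1..n.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  label_components_cpp(mask, as.integer(connectivity))
}

#' Exact Euclidean distance transform
#'
#' Distance (in pixels) from every pixel to the nearest `TRUE` pixel of
#' `feature`, plus the linear index of that nearest pixel (0 when the mask is
#' empty) so labels can be propagated.
#'
#' @param feature logical matrix of feature pixels.
#' @return list with `dist` (numeric matrix) and `nearest` (integer matrix).
#' @export
distance_transform <- function(feature) {
  stopifnot(is.logical(feature))
  edt_cpp(feature)
}

#' Split touching binary objects with a seeded watershed
#'
#' The distance transform of the mask is lightly smoothed, its regional
#' maxima (merged within a 1-pixel radius) seed Meyer's flooding of the
#' negated distance, and each object is re-labelled by catchment basin.
#' Components containing a single seed are left intact.
#'
#' @param mask logical matrix of foreground pixels.
#' @param smooth_sigma_px smoothing applied to the distance map before
#'   maxima detection (stabilizes digital-ellipse ridges).
#' @return integer label matrix.
#' @export
watershed_split <- function(mask, smooth_sigma_px = 1) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dt <- edt_cpp(!mask)$dist     # distance to background
  dt[!mask] <- 0
  dts <- gaussian_blur(dt, smooth_sigma_px)
  dts[!mask] <- 0
  mx <- regional_maxima_cpp(dts, mask)
  # 1-px-radius maxima merge: dilate maxima then label, so maxima closer than
  # one pixel share a seed
  mxd <- grey_dilate_cpp(matrix(as.numeric(mx), nrow(mx)), 1.5) > 0 & mask
  seeds <- label_components_cpp(mxd, 8L)
  seeds[!mx] <- 0L
  watershed_cpp(-dts, seeds, mask)
}

#' Filter labelled particles by area
#'
#' @param labels integer label matrix.
#' @param min_px,max_px inclusive area bounds in pixels.
#' @return list with `labels` (survivors relabelled 1..n) and `areas_px`
#'   (areas of the surviving particles).
#' @export
filter_by_area <- function(labels, min_px, max_px) {
  stopifnot(min_px <= max_px)
  n <- max(labels)
  if (n == 0)
    return(list(labels = labels, areas_px = integer(0)))
  areas <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(areas >= min_px & areas <= max_px)
  map <- integer(n + 1L)
  map[keep + 1L] <- seq_along(keep)
  out <- matrix(map[labels + 1L], nrow(labels), ncol(labels))
  list(labels = out, areas_px = areas[keep])
}

#' Remove small objects and fill small holes in a binary mask
#'
#' Positive components smaller than `min_object_px` are removed; background
#' components (holes, i.e. background regions not touching the image border)
#' smaller than `min_hole_px` are filled.
#'
#' @param mask logical matrix.
#' @param min_object_px,min_hole_px pixel-area thresholds; components and
#'   holes strictly smaller than these are removed/filled.
#' @export
clean_mask <- function(mask, min_object_px = 0, min_hole_px = 0) {
  stopifnot(is.logical(mask))
  if (min_object_px > 0 && any(mask)) {
    lab <- label_components_cpp(mask, 8L)
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    small <- which(areas < min_object_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  if (min_hole_px > 0 && any(!mask)) {
    bg <- label_components_cpp(!mask, 4L)
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border <- border[border > 0]
    areas <- tabulate(bg[bg > 0], nbins = max(bg))
    fill_ids <- setdiff(which(areas < min_hole_px), border)
    if (length(fill_ids))
      mask[bg %in% fill_ids] <- TRUE
  }
  mask
}
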