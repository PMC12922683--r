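#' Parameters for DAPI nuclei counting
#'
#' The counting chain is: difference-of-Gaussians filter, binarization at a
#' triangle-algorithm threshold, watershed separation of touching nuclei,
#' and a particle size filter of 10--250 pixels (closed interval).  The DoG
#' scales are not part of the published chain; defaults follow the rule of
#' thumb sigma_small = 0.3x and sigma_large = 1.0x the expected nucleus
#' radius in pixels.
#'
#' @param sigma_small_px,sigma_large_px DoG scales in pixels
#'   (`sigma_small < sigma_large`).
#' @param min_area_px,max_area_px inclusive particle-area bounds (defaults
#'   10 and 250 pixels).
#' @param apply_watershed separate touching nuclei before the size filter.
#' @param expected_radius_px if given, overrides the sigmas with
#'   `0.3 * radius` and `1.0 * radius`.
#' @return object of class `nuclei_count_params`.
#' @export
nuclei_count_params <- function(sigma_small_px = 1.5, sigma_large_px = 5,
                                min_area_px = 10L, max_area_px = 250L,
                                apply_watershed = TRUE,
                                expected_radius_px = NULL) {
  if (!is.null(expected_radius_px)) {
    sigma_small_px <- 0.3 * expected_radius_px
    sigma_large_px <- 1.0 * expected_radius_px
  }
  stopifnot(sigma_small_px > 0, sigma_large_px > 0,
            sigma_small_px < sigma_large_px,
            min_area_px > 0, max_area_px > 0, min_area_px < max_area_px)
  structure(list(sigma_small_px = sigma_small_px,
                 sigma_large_px = sigma_large_px,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 apply_watershed = isTRUE(apply_watershed)),
            class = "nuclei_count_params")
}

#' Difference-of-Gaussians band-pass filter
#'
#' `blur(sigma_small) - blur(sigma_large)`.  Linear in the input and exactly
#' removes any additive constant, which is what makes the downstream count
#' offset-invariant.
#'
#' @param plane numeric matrix or [image_plane()].
#' @param params a [nuclei_count_params()] (only the sigmas are used).
#' @return numeric matrix of the same shape.
#' @export
difference_of_gaussians <- function(plane, params = nuclei_count_params()) {
  m <- as_plane_matrix(plane)
  if (any(!is.finite(m))) stop("image contains non-finite pixels")
  gaussian_blur(m, params$sigma_small_px) -
    gaussian_blur(m, params$sigma_large_px)
}

#' Triangle-algorithm threshold of an intensity histogram
#'
#' Draws the line from the histogram peak to the farthest nonempty tail bin
#' and returns the bin position maximizing the perpendicular distance from
#' the histogram curve to that line.  Ties (equal distance, or two equal
#' extreme peaks) break to the lowest qualifying bin.  The returned
#' threshold lies strictly between the peak and tail positions.
#'
#' @param counts nonnegative histogram counts per bin.
#' @param mids optional bin positions (defaults to `seq_along(counts)`).
#' @return threshold value on the `mids` scale.
#' @export
triangle_threshold <- function(counts, mids = seq_along(counts)) {
  stopifnot(length(counts) == length(mids), all(counts >= 0))
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2)
    stop("triangle threshold needs at least two nonempty bins")
  peak <- which.max(counts)             # lowest bin on ties
  tail_bin <- nonempty[which.max(abs(nonempty - peak))]
  if (tail_bin == peak) stop("degenerate histogram")
  lo <- min(peak, tail_bin); hi <- max(peak, tail_bin)
  cand <- setdiff(lo:hi, c(peak, tail_bin))
  if (length(cand) == 0) cand <- lo:hi
  # perpendicular distance from (x, h(x)) to line through peak and tail
  x1 <- peak; y1 <- counts[peak]; x2 <- tail_bin; y2 <- counts[tail_bin]
  d <- abs((y2 - y1) * cand - (x2 - x1) * counts[cand] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  best <- cand[which.max(d)]
  mids[best]
}

#' Count DAPI-positive nuclei in a region of interest
#'
#' Applies the full counting chain and returns the surviving-particle count
#' and a label grid.  A blank image yields a count of zero (not an error);
#' an empty ROI is an error.  The size filter is applied after watershed
#' separation, matching the stated order of operations.
#'
#' @param plane DAPI image (matrix or [image_plane()]).
#' @param roi optional [roi()] or logical mask; `NULL` means the whole
#'   image.
#' @param params a [nuclei_count_params()].
#' @param n_bins histogram bins used for the triangle threshold.
#' @return list with `count`, `labels` (integer grid, one positive label per
#'   surviving particle), `threshold`, and `density_warning` (`TRUE` when
#'   more than half of the ROI is above threshold, flagging fields too dense
#'   to count reliably).
#' @export
count_nuclei <- function(plane, roi = NULL, params = nuclei_count_params(),
                         n_bins = 256) {
  m <- as_plane_matrix(plane)
  rmask <- roi_mask(roi, dim(m))
  if (!any(rmask)) stop("empty ROI")
  dog <- difference_of_gaussians(m, params)
  vals <- dog[rmask]
  rng <- range(vals)
  empty <- list(count = 0L, labels = matrix(0L, nrow(m), ncol(m)),
                threshold = NA_real_, density_warning = FALSE)
  if (diff(rng) <= 0) return(empty)   # constant (blank) image
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(vals, br, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  if (sum(counts > 0) < 2) return(empty)
  thr <- triangle_threshold(counts, mids)
  fg <- dog > thr & rmask
  if (!any(fg)) return(empty)
  if (params$apply_watershed) {
    labels <- watershed_split(fg)
  } else {
    labels <- label_components(fg, 8)
  }
  flt <- filter_by_area(labels, params$min_area_px, params$max_area_px)
  list(count = length(flt$areas_px), labels = flt$labels, threshold = thr,
       density_warning = mean(fg[rmask]) > 0.5)
}
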