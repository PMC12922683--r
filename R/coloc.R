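#' Background estimation from a low-expression region
#'
#' Mean intensity over a region chosen for low expression of the marker;
#' subtracted from the whole image before colocalization analysis.
#'
#' @param plane image (matrix or [image_plane()]).
#' @param low_expression_region [roi()] or logical mask.
#' @return scalar background estimate.
#' @export
estimate_background <- function(plane, low_expression_region) {
  m <- as_plane_matrix(plane)
  rmask <- roi_mask(low_expression_region, dim(m))
  if (!any(rmask)) stop("empty low-expression region")
  mean(m[rmask])
}

#' Manders split colocalization coefficients
#'
#' Both images are background-subtracted with negatives clipped to zero
#' (required for coefficients bounded in \[0, 1\]).  M1 is the fraction of
#' channel-A intensity lying on pixels where channel B is positive; M2 is
#' the converse.  A channel with zero total intensity in the ROI yields a
#' missing (`NA`) coefficient, not 0.
#'
#' @param a,b image planes of the two channels (same shape).
#' @param roi optional [roi()] or logical mask.
#' @param bg_a,bg_b nonnegative background levels subtracted from `a`, `b`.
#' @param label region label for the result row.
#' @return one-row data frame: `region`, `background_A`, `background_B`,
#'   `M1`, `M2`, `n_pixels`.
#' @examples
#' r <- manders_coefficients(matrix(c(10, 0, 5, 0), 2),
#'                           matrix(c(0, 0, 7, 2), 2))
#' c(r$M1, r$M2)  # 1/3, 7/9
#' @export
manders_coefficients <- function(a, b, roi = NULL, bg_a = 0, bg_b = 0,
                                 label = NULL) {
  ma <- as_plane_matrix(a); mb <- as_plane_matrix(b)
  stopifnot(identical(dim(ma), dim(mb)), bg_a >= 0, bg_b >= 0)
  rmask <- roi_mask(roi, dim(ma))
  if (is.null(label))
    label <- if (inherits(roi, "roi")) roi$label else "ROI"
  ap <- pmax(ma[rmask] - bg_a, 0)
  bp <- pmax(mb[rmask] - bg_b, 0)
  sa <- sum(ap); sb <- sum(bp)
  m1 <- if (sa > 0) sum(ap[bp > 0]) / sa else NA_real_
  m2 <- if (sb > 0) sum(bp[ap > 0]) / sb else NA_real_
  data.frame(region = label, background_A = bg_a, background_B = bg_b,
             M1 = m1, M2 = m2, n_pixels = sum(rmask),
             stringsAsFactors = FALSE)
}

#' Binary overlap overlay of two background-subtracted channels
#'
#' Labels every pixel positive after background subtraction: 1 = A only,
#' 2 = B only, 3 = overlap, 0 = neither.
#'
#' @inheritParams manders_coefficients
#' @return integer matrix of overlay classes.
#' @export
binary_overlay <- function(a, b, bg_a = 0, bg_b = 0) {
  ma <- as_plane_matrix(a); mb <- as_plane_matrix(b)
  stopifnot(identical(dim(ma), dim(mb)))
  pa <- (ma - bg_a) > 0
  pb <- (mb - bg_b) > 0
  out <- matrix(0L, nrow(ma), ncol(ma))
  out[pa & !pb] <- 1L
  out[!pa & pb] <- 2L
  out[pa & pb] <- 3L
  out
}

#' Band specification for distance-banded sub-regions
#'
#' Default edges follow the printed proximal/medial/distal convention:
#' proximal `[0, 30)` um, medial `[30, 60)` um, distal `> 70` um from the
#' reference layer, leaving pixels at 60--70 um unassigned (the printed
#' edges contain this gap); set `merge_gap = TRUE` to fold the gap into the
#' distal band.
#'
#' @param reference logical mask (or [roi()]) of the reference layer (e.g.
#'   the pyramidal cell layer).
#' @param edges_um four increasing edges `c(e1, e2, e3, e4)`: proximal
#'   `[e1, e2)`, medial `[e2, e3)`, gap `[e3, e4]`, distal `> e4`.
#' @param merge_gap include the gap in the distal band.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(reference, edges_um = c(0, 30, 60, 70),
                      merge_gap = FALSE) {
  stopifnot(length(edges_um) == 4, all(diff(edges_um) > 0))
  structure(list(reference = reference, edges_um = edges_um,
                 merge_gap = isTRUE(merge_gap)),
            class = "band_spec")
}

#' Divide a region into distance bands from a reference layer
#'
#' Every ROI pixel is assigned by its Euclidean distance to the nearest
#' reference-layer pixel.  Bands partition the ROI (minus the printed-edge
#' gap) and are pairwise disjoint.
#'
#' @param roi a [roi()] or logical mask to subdivide.
#' @param spec a [band_spec()].
#' @param pixel_size_um micrometres per pixel (taken from the ROI when
#'   available).
#' @return named list of [roi()] objects (`proximal`, `medial`, `distal`);
#'   the unassigned gap mask is attached as attribute `"gap"`.
#' @export
band_roi <- function(roi, spec, pixel_size_um = NULL) {
  stopifnot(inherits(spec, "band_spec"))
  rmask <- roi_mask(roi, NULL)
  ps <- pixel_size_um %||% pixel_size(roi) %||% 0.5
  ref <- roi_mask(spec$reference, dim(rmask))
  if (!any(ref)) stop("empty reference mask")
  d_um <- distance_transform(ref)$dist * ps
  e <- spec$edges_um
  base <- if (inherits(roi, "roi")) roi$label else "ROI"
  bands <- list(
    proximal = rmask & d_um >= e[1] & d_um < e[2],
    medial   = rmask & d_um >= e[2] & d_um < e[3],
    distal   = rmask & d_um > e[4]
  )
  gap <- rmask & d_um >= e[3] & d_um <= e[4]
  if (spec$merge_gap) {
    bands$distal <- bands$distal | gap
    gap <- matrix(FALSE, nrow(rmask), ncol(rmask))
  }
  out <- lapply(names(bands), function(nm)
    roi(bands[[nm]], paste(base, nm), ps))
  names(out) <- names(bands)
  attr(out, "gap") <- gap
  out
}
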