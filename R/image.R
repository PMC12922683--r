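#' Image planes, stacks and regions of interest
#'
#' An `image_plane` is a numeric matrix of intensities (arbitrary units) with
#' a physical pixel size in micrometres; an `image_stack` is a named list of
#' planes sharing one geometry (one plane per stain plus DAPI).  A `roi` is a
#' named pixel mask, optionally built from GeoJSON-style polygons with
#' exclusion sub-regions already subtracted.
#'
#' @param data numeric matrix of pixel intensities.
#' @param pixel_size_um physical size of one pixel edge, micrometres.
#' @param channel optional channel name.
#' @return `image_plane()` returns the matrix with class `image_plane` and a
#'   `pixel_size_um` attribute.
#' @examples
#' p <- image_plane(matrix(0, 8, 8), pixel_size_um = 0.5)
#' pixel_size(p)
#' @export
image_plane <- function(data, pixel_size_um = 0.5, channel = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(data, pixel_size_um = pixel_size_um, channel = channel,
            class = c("image_plane", class(data)))
}

#' @rdname image_plane
#' @param channels named list of matrices or image planes.
#' @export
image_stack <- function(channels, pixel_size_um = 0.5) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channels must share one geometry")
  planes <- lapply(names(channels), function(nm)
    image_plane(unclass_plane(channels[[nm]]), pixel_size_um, channel = nm))
  names(planes) <- names(channels)
  structure(list(channels = planes, pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @rdname image_plane
#' @param x an image plane, stack or ROI.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps) && is.list(x)) ps <- x$pixel_size_um
  ps
}

unclass_plane <- function(x) {
  attr(x, "pixel_size_um") <- NULL
  attr(x, "channel") <- NULL
  class(x) <- "matrix"
  matrix(as.numeric(x), nrow(x), ncol(x))
}

as_plane_matrix <- function(x) {
  if (inherits(x, "image_plane")) unclass_plane(x) else {
    stopifnot(is.matrix(x))
    x
  }
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @rdname image_plane
#' @param mask logical matrix of member pixels.
#' @param label region label, e.g. `"CA1 SO"`.
#' @param exclusions optional list of logical matrices removed from the mask.
#' @export
roi <- function(mask, label = "ROI", pixel_size_um = 0.5, exclusions = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.null(exclusions)) {
    for (ex in exclusions) {
      stopifnot(identical(dim(ex), dim(mask)))
      mask <- mask & !ex
    }
  }
  structure(list(mask = mask, label = label, pixel_size_um = pixel_size_um),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi '%s': %d px (%.3g um/px)\n", x$label, sum(x$mask),
              x$pixel_size_um))
  invisible(x)
}

roi_mask <- function(x, dim_ref = NULL) {
  m <- if (inherits(x, "roi")) x$mask else x
  if (is.null(m)) {
    stopifnot(!is.null(dim_ref))
    m <- matrix(TRUE, dim_ref[1], dim_ref[2])
  }
  stopifnot(is.logical(m))
  m
}

#' Rasterize a polygon into a pixel mask
#'
#' Even-odd scanline fill.  Polygon vertices are in micrometre coordinates
#' (`x` along columns, `y` along rows, origin at the top-left pixel centre).
#'
#' @param xy two-column matrix of polygon vertices (um).
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param pixel_size_um micrometres per pixel.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(xy, dim, pixel_size_um = 0.5) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  nr <- dim[1]; nc <- dim[2]
  px <- xy[, 1] / pixel_size_um
  py <- xy[, 2] / pixel_size_um
  out <- matrix(FALSE, nr, nc)
  n <- length(px)
  jx <- c(n, seq_len(n - 1))
  for (i in seq_len(nr)) {
    yr <- i - 1
    x1 <- px; y1 <- py; x2 <- px[jx]; y2 <- py[jx]
    sel <- (y1 > yr) != (y2 > yr)
    if (!any(sel)) next
    xi <- x1[sel] + (yr - y1[sel]) / (y2[sel] - y1[sel]) * (x2[sel] - x1[sel])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      lo <- max(1L, ceiling(xi[k] + 1))
      hi <- min(nc, floor(xi[k + 1] + 1))
      if (lo <= hi) out[i, lo:hi] <- TRUE
    }
  }
  out
}

#' Read regions of interest from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon features.  A feature property
#' `name` (or `classification$name`) provides the region label; holes in a
#' polygon are treated as exclusion sub-regions.
#'
#' @param path GeoJSON file.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param pixel_size_um micrometres per pixel.
#' @return list of [roi()] objects.
#' @export
read_rois_geojson <- function(path, dim, pixel_size_um = 0.5) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    rings <- lapply(geom$coordinates, function(r)
      do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]]))))
    mask <- rasterize_polygon(rings[[1]], dim, pixel_size_um)
    excl <- NULL
    if (length(rings) > 1)
      excl <- lapply(rings[-1], rasterize_polygon, dim = dim,
                     pixel_size_um = pixel_size_um)
    lbl <- f$properties$name
    if (is.null(lbl)) lbl <- f$properties$classification$name
    if (is.null(lbl)) lbl <- sprintf("ROI%d", length(out) + 1L)
    out[[lbl]] <- roi(mask, lbl, pixel_size_um, exclusions = excl)
  }
  out
}

#' Plain-text raster I/O
#'
#' Images are exchanged as headerless CSV matrices with a JSON sidecar
#' (`<file>.json`) holding the pixel size and channel name, so that every
#' artefact in a run directory is human-readable text.
#'
#' @param plane an [image_plane()].
#' @param path output file.
#' @export
write_image_csv <- function(plane, path) {
  m <- as_plane_matrix(plane)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(pixel_size_um = pixel_size(plane) %||% 0.5,
               channel = attr(plane, "channel"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  meta_path <- paste0(path, ".json")
  ps <- 0.5; ch <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$pixel_size_um)) ps <- meta$pixel_size_um
    ch <- meta$channel
  }
  image_plane(m, ps, channel = ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
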