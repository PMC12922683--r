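#' Configure a synthetic multiplex tissue scene
#'
#' The generator emulates a single imaging plane of multiplex-stained tissue:
#' DAPI-stained elliptical nuclei of controlled area, one marker channel per
#' cell class (somatic, membranous, nuclear or vessel-ring staining), and a
#' target channel in which each cell carries signal concentrated
#' perinuclearly (a Gaussian blob offset to one side of the nucleus when
#' `golgi_polarized`), on top of a uniform control background plus a diffuse
#' neuropil layer.  Noise is additive Gaussian with standard deviation equal
#' to `noise_frac` of the local mean, clipped at zero.  Autofluorescent
#' puncta are added identically to every channel.
#'
#' The diffuse layer and control background underlie somas as well: in a
#' projected section, neuropil signal overlaps cell bodies, and this is what
#' the downstream low-area median correction removes from disc means.
#'
#' @param image_size_px `c(nrow, ncol)` in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.5).
#' @param cell_classes data frame with columns `class_name`,
#'   `marker_channel`, `marker_pattern` (one of `"somatic"`, `"membranous"`,
#'   `"nuclear"`, `"vessel_ring"`), `true_target_mean`, `count`; optional
#'   columns `soma_expansion_um` (cytoplasm width beyond the nucleus, default
#'   3), `nucleus_area_um2_min`/`_max` (per-class override of the global
#'   range) and `inner_channel` (inner-ring channel of vessel scenes,
#'   default `"CD31"`).
#' @param nucleus_area_um2_range `c(min, max)` nucleus areas in um^2.
#' @param diffuse_level uniform neuropil signal added to the target channel.
#' @param control_background background common to all stained and control
#'   images.
#' @param puncta_count number of bright autofluorescent puncta added to
#'   every channel.
#' @param golgi_polarized if `TRUE`, per-cell target signal is a Gaussian
#'   blob (sd 1.5 um) whose centre is offset 1--2 um beyond the nucleus edge
#'   on a random side; if `FALSE`, signal is uniform over the soma.  Either
#'   way the mean over the soma mask equals `true_target_mean` exactly
#'   before noise.
#' @param overlap optional data frame (`class_name`, `host_class`,
#'   `fraction`) forcing that fraction of a class's cells to be placed with
#'   their nucleus tangent to the nucleus of a host-class cell, so that
#'   their expanded discs spill into the host soma.  Host classes must be
#'   listed before overlapping classes; later-listed classes are composited
#'   on top (occlusion, as for a cell lying over another in projection).
#' @param noise_frac noise standard deviation as a fraction of local mean.
#' @param seed integer seed; identical configs give bit-identical scenes.
#' @return an object of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(image_size_px = c(512, 512),
                              pixel_size_um = 0.5,
                              cell_classes = NULL,
                              nucleus_area_um2_range = c(30, 70),
                              diffuse_level = 0,
                              control_background = 0,
                              puncta_count = 0,
                              golgi_polarized = TRUE,
                              overlap = NULL,
                              noise_frac = 0.02,
                              seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 8),
            pixel_size_um > 0,
            length(nucleus_area_um2_range) == 2,
            nucleus_area_um2_range[1] > 0,
            nucleus_area_um2_range[1] < nucleus_area_um2_range[2],
            diffuse_level >= 0, control_background >= 0,
            puncta_count >= 0, noise_frac >= 0)
  if (is.null(cell_classes))
    cell_classes <- data.frame(class_name = character(0),
                               marker_channel = character(0),
                               marker_pattern = character(0),
                               true_target_mean = numeric(0),
                               count = integer(0))
  req <- c("class_name", "marker_channel", "marker_pattern",
           "true_target_mean", "count")
  stopifnot(all(req %in% names(cell_classes)))
  stopifnot(all(cell_classes$marker_pattern %in%
                  c("somatic", "membranous", "nuclear", "vessel_ring")),
            all(cell_classes$true_target_mean >= 0),
            all(cell_classes$count >= 0),
            !anyDuplicated(cell_classes$class_name))
  if (is.null(cell_classes$soma_expansion_um))
    cell_classes$soma_expansion_um <- rep(3, nrow(cell_classes))
  if (is.null(cell_classes$inner_channel))
    cell_classes$inner_channel <- rep("CD31", nrow(cell_classes))
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 cell_classes = cell_classes,
                 nucleus_area_um2_range = nucleus_area_um2_range,
                 diffuse_level = diffuse_level,
                 control_background = control_background,
                 puncta_count = as.integer(puncta_count),
                 golgi_polarized = isTRUE(golgi_polarized),
                 overlap = overlap,
                 noise_frac = noise_frac,
                 seed = as.integer(seed)),
            class = "tissue_sim_config")
}

# intensity scale of the synthetic stains (arbitrary units)
DAPI_AMPLITUDE <- 100
MARKER_AMPLITUDE <- 50
PUNCTA_AMPLITUDE <- 40

ellipse_idx_in <- function(nr, nc, cy, cx, ry, rx) {
  i0 <- max(1L, floor(cy - ry)); i1 <- min(nr, ceiling(cy + ry))
  j0 <- max(1L, floor(cx - rx)); j1 <- min(nc, ceiling(cx + rx))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  inside <- outer(((ii - cy) / ry)^2, ((jj - cx) / rx)^2, "+") <= 1
  idx <- (rep(jj, each = length(ii)) - 1L) * nr + rep(ii, times = length(jj))
  idx[as.vector(inside)]
}

add_noise <- function(img, frac) {
  if (frac <= 0) return(img)
  n <- length(img)
  pmax(img + stats::rnorm(n) * (frac * img), 0)
}

place_puncta <- function(nr, nc, count, radius_px = 2, min_dist_px = 8) {
  if (count == 0) return(NULL)
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < count && tries < 1000 * count) {
    tries <- tries + 1
    cand <- c(stats::runif(1, radius_px + 1, nr - radius_px),
              stats::runif(1, radius_px + 1, nc - radius_px))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
          min_dist_px) {
      pts <- rbind(pts, cand)
    }
  }
  if (nrow(pts) < count) stop("could not place puncta without overlap")
  pts
}

#' Generate a synthetic multiplex tissue image with ground truth
#'
#' @param config a [tissue_sim_config()].
#' @return list with elements `stack` (an [image_stack()] whose channels are
#'   `DAPI`, one per marker channel, and `target`), `truth` (ground-truth
#'   data frame: `cell_id`, `class_name`, `x_um`, `y_um`, `nucleus_area_um2`,
#'   `true_target_mean`, plus image-level attributes `diffuse_level`,
#'   `control_background`, `seed`), and `masks` (list: `nuclei` and `soma`
#'   label matrices keyed by `cell_id`, and `marker_positive`, a named list
#'   of logical ground-truth staining masks per channel).
#' @export
generate_tissue_image <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  withr::with_seed(config$seed, generate_tissue_image_impl(config))
}

generate_tissue_image_impl <- function(config) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  ps <- config$pixel_size_um
  cls <- config$cell_classes

  # ---- sample cell geometry and place cells ------------------------------
  cells <- list()
  placed <- matrix(numeric(0), ncol = 4) # cy, cx, reff (px), id
  for (ci in seq_len(nrow(cls))) {
    cl <- cls[ci, ]
    n <- cl$count
    if (n == 0) next
    rng <- config$nucleus_area_um2_range
    if (!is.null(cls$nucleus_area_um2_min) &&
        is.finite(cl$nucleus_area_um2_min))
      rng <- c(cl$nucleus_area_um2_min, cl$nucleus_area_um2_max)
    ov_frac <- 0; host <- NULL
    if (!is.null(config$overlap)) {
      orow <- config$overlap[config$overlap$class_name == cl$class_name, ]
      if (nrow(orow) == 1) {
        ov_frac <- orow$fraction
        host <- orow$host_class
        if (!host %in% vapply(cells, `[[`, "", "class_name"))
          stop(sprintf("overlap host class '%s' must be placed before '%s'",
                       host, cl$class_name))
      }
    }
    n_overlap <- round(ov_frac * n)
    for (k in seq_len(n)) {
      area_um2 <- stats::runif(1, rng[1], rng[2])
      aspect <- stats::runif(1, 1, 1.6)
      b_um <- sqrt(area_um2 / (pi * aspect))
      a_um <- aspect * b_um
      if (stats::runif(1) < 0.5) { tmp <- a_um; a_um <- b_um; b_um <- tmp }
      rx <- a_um / ps; ry <- b_um / ps
      reff <- max(rx, ry) + cl$soma_expansion_um / ps
      ok <- FALSE
      for (try in 1:300) {
        if (k <= n_overlap) {
          hosts <- which(vapply(cells, `[[`, "", "class_name") == host)
          h <- cells[[sample(hosts, 1)]]
          ang <- stats::runif(1, 0, 2 * pi)
          # centre offset beyond the host nucleus edge: default tangent
          # nuclei; offset_um places the nucleus inside the host cytoplasm
          off_px <- if (!is.null(orow$offset_um) && is.finite(orow$offset_um))
            orow$offset_um / ps else sqrt(rx * ry)
          d <- sqrt(h$area_px / pi) + off_px
          cy <- h$cy + d * sin(ang); cx <- h$cx + d * cos(ang)
          skip <- h$id
        } else {
          cy <- stats::runif(1, reff + 1, nr - reff)
          cx <- stats::runif(1, reff + 1, nc - reff)
          skip <- -1L
        }
        if (cy < reff + 1 || cy > nr - reff || cx < reff + 1 ||
            cx > nc - reff) next
        if (nrow(placed) > 0) {
          keep <- placed[, 4] != skip
          if (any(keep)) {
            dd <- sqrt((placed[keep, 1] - cy)^2 + (placed[keep, 2] - cx)^2)
            if (any(dd < placed[keep, 3] + reff)) next
          }
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("could not place all cells of class '%s': scene too dense",
                     cl$class_name))
      id <- length(cells) + 1L
      cells[[id]] <- list(id = id, class_name = cl$class_name,
                          marker_channel = cl$marker_channel,
                          marker_pattern = cl$marker_pattern,
                          inner_channel = cl$inner_channel,
                          true_target_mean = cl$true_target_mean,
                          cy = cy, cx = cx, rx = rx, ry = ry,
                          soma_um = cl$soma_expansion_um,
                          area_px = pi * rx * ry)
      placed <- rbind(placed, c(cy, cx, reff, id))
    }
  }

  # ---- rasterize nuclei and somas (later cells overwrite: occlusion) -----
  nuclei <- matrix(0L, nr, nc)
  soma <- matrix(0L, nr, nc)
  for (cell in cells) {
    nidx <- ellipse_idx_in(nr, nc, cell$cy, cell$cx, cell$ry, cell$rx)
    sidx <- ellipse_idx_in(nr, nc, cell$cy, cell$cx,
                           cell$ry + cell$soma_um / ps,
                           cell$rx + cell$soma_um / ps)
    nuclei[nidx] <- cell$id
    soma[sidx] <- cell$id
  }

  # ---- channels ----------------------------------------------------------
  channel_names <- unique(c(unlist(lapply(cells, function(cell) {
    if (cell$marker_pattern == "vessel_ring")
      c(cell$marker_channel, cell$inner_channel) else cell$marker_channel
  })), cls$marker_channel))
  channel_names <- channel_names[!is.na(channel_names) & nzchar(channel_names)]
  chans <- list(DAPI = matrix(0, nr, nc))
  for (nm in channel_names) chans[[nm]] <- matrix(0, nr, nc)
  chans$target <- matrix(config$control_background + config$diffuse_level,
                         nr, nc)
  marker_pos <- lapply(chans[channel_names], function(m)
    matrix(FALSE, nr, nc))

  chans$DAPI[nuclei > 0] <- DAPI_AMPLITUDE

  for (cell in cells) {
    own_soma <- which(soma == cell$id)
    own_nuc <- which(nuclei == cell$id)
    pat <- cell$marker_pattern
    if (pat == "somatic") {
      midx <- own_soma
    } else if (pat == "nuclear") {
      midx <- own_nuc
    } else if (pat == "membranous") {
      outer_idx <- ellipse_idx_in(nr, nc, cell$cy, cell$cx,
                                  cell$ry + cell$soma_um / ps,
                                  cell$rx + cell$soma_um / ps)
      inner_idx <- ellipse_idx_in(nr, nc, cell$cy, cell$cx,
                                  cell$ry + (cell$soma_um - 1) / ps,
                                  cell$rx + (cell$soma_um - 1) / ps)
      midx <- setdiff(outer_idx, inner_idx)
    } else { # vessel_ring: lumen + endothelial inner ring + own mural ring
      ang <- stats::runif(1, 0, 2 * pi)
      lumen_um <- 3; endo_w <- 1.5; mural_w <- 2
      vd <- (lumen_um + endo_w + mural_w / 2) / ps
      vy <- cell$cy + vd * sin(ang); vx <- cell$cx + vd * cos(ang)
      ring <- function(r_out, r_in) {
        setdiff(ellipse_idx_in(nr, nc, vy, vx, r_out / ps, r_out / ps),
                ellipse_idx_in(nr, nc, vy, vx, r_in / ps, r_in / ps))
      }
      inner <- ring(lumen_um + endo_w, lumen_um)
      midx <- ring(lumen_um + endo_w + mural_w, lumen_um + endo_w)
      chans[[cell$inner_channel]][inner] <- MARKER_AMPLITUDE
      marker_pos[[cell$inner_channel]][inner] <- TRUE
    }
    chans[[cell$marker_channel]][midx] <- MARKER_AMPLITUDE
    marker_pos[[cell$marker_channel]][midx] <- TRUE

    # target signal over the cell's own soma pixels, mean == true_target_mean
    if (cell$true_target_mean > 0 && length(own_soma) > 0) {
      if (config$golgi_polarized) {
        th <- stats::runif(1, 0, 2 * pi)
        # radius of the nucleus ellipse along direction th, plus 1-2 um
        rth <- 1 / sqrt((cos(th) / cell$rx)^2 + (sin(th) / cell$ry)^2)
        off <- rth + stats::runif(1, 1, 2) / ps
        by <- cell$cy + off * sin(th); bx <- cell$cx + off * cos(th)
        rr <- ((own_soma - 1) %% nr) + 1
        cc <- ((own_soma - 1) %/% nr) + 1
        g <- exp(-((rr - by)^2 + (cc - bx)^2) / (2 * (1.5 / ps)^2))
        sg <- sum(g)
        if (sg <= 0) g <- rep(1, length(own_soma)) else g <- g / sg
        chans$target[own_soma] <- config$control_background +
          config$diffuse_level + g * cell$true_target_mean * length(own_soma)
      } else {
        chans$target[own_soma] <- config$control_background +
          config$diffuse_level + cell$true_target_mean
      }
    }
  }

  # ---- puncta (identical in every channel) and noise ---------------------
  pts <- place_puncta(nr, nc, config$puncta_count)
  if (!is.null(pts)) {
    for (k in seq_len(nrow(pts))) {
      idx <- ellipse_idx_in(nr, nc, pts[k, 1], pts[k, 2], 2, 2)
      for (nm in names(chans)) chans[[nm]][idx] <- chans[[nm]][idx] +
          PUNCTA_AMPLITUDE
    }
  }
  chans <- lapply(chans, add_noise, frac = config$noise_frac)

  truth <- data.frame(
    cell_id = vapply(cells, `[[`, 0L, "id"),
    class_name = vapply(cells, `[[`, "", "class_name"),
    x_um = vapply(cells, `[[`, 0, "cx") * ps,
    y_um = vapply(cells, `[[`, 0, "cy") * ps,
    nucleus_area_um2 = vapply(cells, function(cell)
      sum(nuclei == cell$id) * ps^2, 0),
    true_target_mean = vapply(cells, `[[`, 0, "true_target_mean"),
    stringsAsFactors = FALSE
  )
  attr(truth, "diffuse_level") <- config$diffuse_level
  attr(truth, "control_background") <- config$control_background
  attr(truth, "seed") <- config$seed

  list(stack = image_stack(chans, ps),
       truth = truth,
       masks = list(nuclei = nuclei, soma = soma,
                    marker_positive = marker_pos))
}

#' Generate a matching control image (no primary antibody)
#'
#' Contains the control background and autofluorescent puncta only, with the
#' same noise model as the stained image: no specific signal.
#'
#' @param config a [tissue_sim_config()].
#' @return an [image_plane()].
#' @export
generate_control_image <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  withr::with_seed(config$seed, {
    nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
    img <- matrix(config$control_background, nr, nc)
    pts <- place_puncta(nr, nc, config$puncta_count)
    if (!is.null(pts)) {
      for (k in seq_len(nrow(pts))) {
        idx <- ellipse_idx_in(nr, nc, pts[k, 1], pts[k, 2], 2, 2)
        img[idx] <- img[idx] + PUNCTA_AMPLITUDE
      }
    }
    image_plane(add_noise(img, config$noise_frac), config$pixel_size_um,
                channel = "control")
  })
}

#' Sparse pixel annotations from a ground-truth mask
#'
#' Samples labelled training pixels for the pixel classifiers: label 1 =
#' background (outside `positive`), label 2 = positive.  Mirrors the sparse
#' manual brush annotations used to train staining classifiers.
#'
#' @param positive logical ground-truth mask of positive staining.
#' @param n_per_class pixels sampled per class.
#' @param seed integer seed.
#' @param exclude optional logical mask never sampled (e.g. ambiguous
#'   boundary pixels).
#' @return integer matrix (0 = unlabelled).
#' @export
sample_annotations <- function(positive, n_per_class = 2000, seed = 1,
                               exclude = NULL) {
  stopifnot(is.logical(positive))
  withr::with_seed(seed, {
    ann <- matrix(0L, nrow(positive), ncol(positive))
    pos <- which(positive)
    neg <- which(!positive)
    if (!is.null(exclude)) {
      pos <- setdiff(pos, which(exclude))
      neg <- setdiff(neg, which(exclude))
    }
    if (length(pos) == 0 || length(neg) == 0)
      stop("both classes must be present in the annotation source")
    ann[sample(neg, min(n_per_class, length(neg)))] <- 1L
    ann[sample(pos, min(n_per_class, length(pos)))] <- 2L
    ann
  })
}

#' Configure a synthetic cluster-by-gene expression matrix
#'
#' @param n_clusters_per_class named integer vector: clusters per class.
#' @param class_mean_expression named numeric vector: query-gene mean per
#'   class (the planted quantity recovered downstream).
#' @param marker_rulebook named list mapping class name to its canonical
#'   marker genes (character vector); see [default_marker_rulebook()].
#' @param noise_sd Gaussian noise added to every expression value.
#' @param query_gene name of the query gene column (default `"Igf2r"`).
#' @param seed integer seed.
#' @export
cluster_sim_config <- function(n_clusters_per_class, class_mean_expression,
                               marker_rulebook, noise_sd = 0,
                               query_gene = "Igf2r", seed = 1L) {
  classes <- names(class_mean_expression)
  stopifnot(length(classes) > 0, !is.null(names(n_clusters_per_class)),
            all(classes %in% names(n_clusters_per_class)),
            all(n_clusters_per_class[classes] >= 1),
            all(class_mean_expression >= 0), noise_sd >= 0)
  for (cl in classes) {
    mk <- marker_rulebook[[cl]]
    if (is.data.frame(mk)) mk <- mk$gene[mk$direction == "high"]
    if (is.null(mk) || length(mk) == 0)
      stop(sprintf("class '%s' has no marker genes", cl))
  }
  structure(list(n_clusters_per_class = n_clusters_per_class,
                 class_mean_expression = class_mean_expression,
                 marker_rulebook = marker_rulebook,
                 noise_sd = noise_sd, query_gene = query_gene,
                 seed = as.integer(seed)),
            class = "cluster_sim_config")
}

#' Generate a synthetic cluster-level expression matrix
#'
#' Each cluster expresses its class's canonical markers high (1 AU), all
#' other genes low (0 AU), and the query gene at the class mean, all plus
#' Gaussian noise of the configured standard deviation.
#'
#' @param config a [cluster_sim_config()].
#' @return list with `matrix` (a [cluster_matrix()]) and `labels` (the
#'   planted class per cluster).
#' @export
generate_cluster_matrix <- function(config) {
  stopifnot(inherits(config, "cluster_sim_config"))
  withr::with_seed(config$seed, {
    classes <- names(config$class_mean_expression)
    genes_of <- lapply(classes, function(cl) {
      mk <- config$marker_rulebook[[cl]]
      if (is.data.frame(mk)) mk$gene[mk$direction == "high"] else mk
    })
    names(genes_of) <- classes
    genes <- unique(c(unlist(genes_of), config$query_gene))
    rows <- unlist(lapply(classes, function(cl)
      sprintf("%s_%d", cl, seq_len(config$n_clusters_per_class[[cl]]))))
    labels <- unlist(lapply(classes, function(cl)
      rep(cl, config$n_clusters_per_class[[cl]])))
    expr <- matrix(0, length(rows), length(genes),
                   dimnames = list(rows, genes))
    for (i in seq_along(rows)) {
      expr[i, genes_of[[labels[i]]]] <- 1
      expr[i, config$query_gene] <- config$class_mean_expression[[labels[i]]]
    }
    if (config$noise_sd > 0)
      expr <- expr + stats::rnorm(length(expr), 0, config$noise_sd)
    meta <- data.frame(cluster = rows, annotation = labels,
                       dataset = "synthetic", stringsAsFactors = FALSE)
    list(matrix = cluster_matrix(expr, meta), labels = labels)
  })
}
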