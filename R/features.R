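#' Configuration of a pixel classifier
#'
#' Describes the multiscale feature bank (Gaussian, Laplacian of Gaussian,
#' gradient magnitude, Hessian determinant, Gaussian-weighted standard
#' deviation), optional local normalization (subtraction of a
#' Gaussian-weighted local mean at a stated scale, compensating uneven
#' staining), the small feed-forward network, and the post-classification
#' cleanup sizes.
#'
#' @param features subset of `"gaussian"`, `"laplacian_of_gaussian"`,
#'   `"gradient_magnitude"`, `"hessian_determinant"`, `"weighted_std"`.
#' @param scales_um strictly increasing smoothing scales in micrometres.
#' @param local_normalization_scale_um optional local-normalization scale
#'   (e.g. 32 for markers with dense somatic staining, 20 for finer ones);
#'   `NULL` disables it.
#' @param hidden hidden-layer width of the classifier network.
#' @param n_iter,learning_rate full-batch Adam training schedule.
#' @param min_object_um2,min_hole_um2 cleanup: positive objects smaller than
#'   `min_object_um2` are removed, holes smaller than `min_hole_um2` filled.
#' @param pixel_size_um fallback pixel size when the classified plane does
#'   not carry one.
#' @param seed integer seed for weight initialization.
#' @export
classifier_config <- function(features = c("gaussian",
                                           "laplacian_of_gaussian",
                                           "gradient_magnitude"),
                              scales_um = c(0.5, 1, 2, 4),
                              local_normalization_scale_um = NULL,
                              hidden = 8L, n_iter = 300L,
                              learning_rate = 0.05,
                              min_object_um2 = 10, min_hole_um2 = 20,
                              pixel_size_um = 0.5, seed = 1L) {
  all_feats <- c("gaussian", "laplacian_of_gaussian", "gradient_magnitude",
                 "hessian_determinant", "weighted_std")
  stopifnot(length(features) >= 1, all(features %in% all_feats),
            length(scales_um) >= 1, all(diff(scales_um) > 0),
            all(scales_um > 0),
            is.null(local_normalization_scale_um) ||
              local_normalization_scale_um > 0,
            hidden >= 1, min_object_um2 >= 0, min_hole_um2 >= 0,
            pixel_size_um > 0)
  structure(list(features = features, scales_um = scales_um,
                 local_normalization_scale_um = local_normalization_scale_um,
                 hidden = as.integer(hidden), n_iter = as.integer(n_iter),
                 learning_rate = learning_rate,
                 min_object_um2 = min_object_um2,
                 min_hole_um2 = min_hole_um2,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "classifier_config")
}

shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp_idx(seq_len(nr) + di, nr)
  cj <- clamp_idx(seq_len(nc) + dj, nc)
  m[ri, cj, drop = FALSE]
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

laplacian4 <- function(m) {
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1) - 4 * m
}

#' Compute the multiscale feature stack for one channel
#'
#' One grid per (feature, scale).  When local normalization is configured, a
#' Gaussian-weighted local mean at that scale is subtracted from the input
#' before feature extraction.  The Laplacian of Gaussian is
#' scale-normalized (multiplied by sigma^2); gradients use central
#' differences of the Gaussian-smoothed image.
#'
#' @param plane image (matrix or [image_plane()]).
#' @param cfg a [classifier_config()].
#' @return named list of feature matrices (`<feature>_s<scale>`), with the
#'   config attached as attribute `"config"`.
#' @export
compute_features <- function(plane, cfg = classifier_config()) {
  m <- as_plane_matrix(plane)
  ps <- pixel_size(plane) %||% cfg$pixel_size_um
  max_scale_px <- max(cfg$scales_um) / ps
  if (2 * ceiling(3 * max_scale_px) + 1 > min(dim(m)))
    stop("feature scale larger than image extent")
  if (!is.null(cfg$local_normalization_scale_um)) {
    ln_px <- cfg$local_normalization_scale_um / ps
    if (2 * ceiling(3 * ln_px) + 1 > min(dim(m)))
      stop("local normalization scale larger than image extent")
    m <- m - gaussian_blur(m, ln_px)
  }
  out <- list()
  for (s_um in cfg$scales_um) {
    s <- s_um / ps
    g <- gaussian_blur(m, s)
    for (f in cfg$features) {
      val <- switch(f,
        gaussian = g,
        laplacian_of_gaussian = s^2 * laplacian4(g),
        gradient_magnitude = {
          gx <- (shift_mat(g, 0, 1) - shift_mat(g, 0, -1)) / 2
          gy <- (shift_mat(g, 1, 0) - shift_mat(g, -1, 0)) / 2
          sqrt(gx^2 + gy^2)
        },
        hessian_determinant = {
          gxx <- shift_mat(g, 0, 1) + shift_mat(g, 0, -1) - 2 * g
          gyy <- shift_mat(g, 1, 0) + shift_mat(g, -1, 0) - 2 * g
          gx <- (shift_mat(g, 0, 1) - shift_mat(g, 0, -1)) / 2
          gxy <- (shift_mat(gx, 1, 0) - shift_mat(gx, -1, 0)) / 2
          gxx * gyy - gxy^2
        },
        weighted_std = {
          v <- gaussian_blur(m^2, s) - g^2
          sqrt(pmax(v, 0))
        })
      out[[sprintf("%s_s%g", f, s_um)]] <- val
    }
  }
  attr(out, "config") <- cfg
  attr(out, "geometry") <- dim(m)
  attr(out, "pixel_size_um") <- ps
  out
}

features_to_matrix <- function(features, idx = NULL) {
  if (is.null(idx)) {
    do.call(cbind, lapply(features, as.vector))
  } else {
    do.call(cbind, lapply(features, function(f) f[idx]))
  }
}

#' Train a pixel classifier on sparse annotations
#'
#' A seeded single-hidden-layer feed-forward network (tanh hidden layer,
#' softmax output) trained by full-batch Adam on standardized features.
#' Identical seeds give identical models.
#'
#' @param features feature stack from [compute_features()].
#' @param annotations integer label matrix: 0 = unlabelled, 1..K = classes
#'   (at least two classes must be present).
#' @param cfg the [classifier_config()] used for the features.
#' @return object of class `pixel_classifier` with the fitted weights,
#'   feature scaling, class codes and training accuracy.
#' @export
train_pixel_classifier <- function(features, annotations,
                                   cfg = attr(features, "config")) {
  stopifnot(is.matrix(annotations))
  idx <- which(annotations > 0)
  y <- as.integer(annotations[idx])
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("annotations must contain at least two classes")
  X <- features_to_matrix(features, idx)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  yi <- match(y, classes)
  K <- length(classes); d <- ncol(X); h <- cfg$hidden; n <- nrow(X)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  withr::with_seed(cfg$seed, {
    W1 <- matrix(stats::rnorm(d * h, 0, 0.5), d, h); b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * K, 0, 0.5), h, K); b2 <- numeric(K)
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- lapply(pars, function(p) p * 0)
    vel <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; lambda <- 1e-4
    lr <- cfg$learning_rate
    for (it in seq_len(cfg$n_iter)) {
      H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, "+"))
      S <- sweep(H %*% pars$W2, 2, pars$b2, "+")
      S <- S - apply(S, 1, max)
      P <- exp(S); P <- P / rowSums(P)
      dS <- (P - Y) / n
      grads <- list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
      grads$W2 <- crossprod(H, dS) + lambda * pars$W2
      grads$b2 <- colSums(dS)
      dH <- (dS %*% t(pars$W2)) * (1 - H^2)
      grads$W1 <- crossprod(X, dH) + lambda * pars$W1
      grads$b1 <- colSums(dH)
      for (nm in names(pars)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^it)
        vhat <- vel[[nm]] / (1 - beta2^it)
        pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, "+"))
    S <- sweep(H %*% pars$W2, 2, pars$b2, "+")
    acc <- mean(max.col(S, ties.method = "first") == yi)
    structure(list(pars = pars, mu = mu, sd = sdv, classes = classes,
                   cfg = cfg, training_accuracy = acc),
              class = "pixel_classifier")
  })
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("pixel_classifier: %d features -> %d hidden -> %d classes (training accuracy %.3f)\n",
              length(x$mu), x$cfg$hidden, length(x$classes),
              x$training_accuracy))
  invisible(x)
}

#' Class posteriors for every pixel
#'
#' @param model a trained `pixel_classifier`.
#' @param features feature stack from [compute_features()] built with the
#'   same configuration as at training time.
#' @return numeric matrix (pixels x classes) of posteriors.
#' @export
predict_pixel_posteriors <- function(model, features) {
  X <- features_to_matrix(features)
  if (ncol(X) != length(model$mu))
    stop("features do not match the training configuration")
  X <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  H <- tanh(sweep(X %*% model$pars$W1, 2, model$pars$b1, "+"))
  S <- sweep(H %*% model$pars$W2, 2, model$pars$b2, "+")
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P / rowSums(P)
}

#' Classify pixels and clean up the positive mask
#'
#' Assigns each pixel its maximum-posterior class, then removes connected
#' positive components smaller than the minimum object size and fills holes
#' smaller than the minimum hole size (both in um^2 from the config).
#'
#' @inheritParams predict_pixel_posteriors
#' @param positive_class class code treated as "positive staining"
#'   (default: the highest class code).
#' @return list with `labels` (integer class grid) and `positive` (cleaned
#'   logical mask).
#' @export
classify_pixels <- function(model, features, positive_class = NULL) {
  dm <- attr(features, "geometry")
  ps <- attr(features, "pixel_size_um") %||% model$cfg$pixel_size_um
  P <- predict_pixel_posteriors(model, features)
  lab <- matrix(model$classes[max.col(P, ties.method = "first")],
                dm[1], dm[2])
  if (is.null(positive_class)) positive_class <- max(model$classes)
  pos <- lab == positive_class
  pos <- clean_mask(pos,
                    min_object_px = model$cfg$min_object_um2 / ps^2,
                    min_hole_px = model$cfg$min_hole_um2 / ps^2)
  list(labels = lab, positive = pos)
}
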