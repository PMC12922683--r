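#' Background-corrected intensity per cell for a region of interest
#'
#' The regional score is `(mean(stained in ROI) - mean(control in ROI)) *
#' area_px / nuclei_count`.  The control mean is measured in the same ROI of
#' a section processed without the primary antibody.  Negative corrected
#' means are retained (reported, not clipped) so that control-dominated
#' regions sort to the bottom of the cohort.
#'
#' @param stained,control image planes sharing geometry and pixel size.
#' @param roi a [roi()] or logical mask.
#' @param nuclei_count number of DAPI+ nuclei in the ROI (must be positive:
#'   regions whose nuclei cannot be counted are excluded upstream).
#' @param label region label recorded in the result (defaults to the ROI's).
#' @return one-row data frame with `region`, `mean_intensity_AU`,
#'   `control_mean_AU`, `area_px`, `nuclei_count`, `intensity_per_cell_AU`.
#' @examples
#' s <- matrix(1, 10, 10); ctl <- matrix(0.3, 10, 10)
#' intensity_per_cell(s, ctl, nuclei_count = 10)$intensity_per_cell_AU # 7
#' @export
intensity_per_cell <- function(stained, control, roi = NULL, nuclei_count,
                               label = NULL) {
  s <- as_plane_matrix(stained); ctl <- as_plane_matrix(control)
  stopifnot(identical(dim(s), dim(ctl)))
  pss <- pixel_size(stained); psc <- pixel_size(control)
  if (!is.null(pss) && !is.null(psc) && !isTRUE(all.equal(pss, psc)))
    stop("stained and control images must share pixel size")
  if (length(nuclei_count) != 1 || is.na(nuclei_count) || nuclei_count <= 0)
    stop("nuclei_count must be positive: ROI with uncountable nuclei is excluded")
  rmask <- roi_mask(roi, dim(s))
  if (!any(rmask)) stop("empty ROI")
  if (is.null(label))
    label <- if (inherits(roi, "roi")) roi$label else "ROI"
  m_s <- mean(s[rmask]); m_c <- mean(ctl[rmask]); area <- sum(rmask)
  data.frame(region = label,
             mean_intensity_AU = m_s,
             control_mean_AU = m_c,
             area_px = area,
             nuclei_count = nuclei_count,
             intensity_per_cell_AU = (m_s - m_c) * area / nuclei_count,
             stringsAsFactors = FALSE)
}

#' Classify regional scores into quartile levels
#'
#' Computes the 25/50/75th percentiles of `intensity_per_cell_AU` across the
#' cohort (linear-interpolation percentile rule, R type 7) and assigns each
#' region a level: low `[p0, p25)`, moderately low `[p25, p50)`, moderately
#' high `[p50, p75)`, high `[p75, p100]`.  A value exactly at a percentile
#' joins the upper level, so a degenerate all-equal cohort is uniformly
#' "high".  Level assignment preserves the ordering of scores and is
#' invariant to rescaling all intensities by a positive constant.
#'
#' @param scores data frame with an `intensity_per_cell_AU` column (rows as
#'   returned by [intensity_per_cell()], typically one per region using
#'   subject means).
#' @return `scores` with a `level` ordered factor
#'   (`low < moderately low < moderately high < high`) and the cohort
#'   percentiles as the `"percentiles"` attribute.
#' @export
classify_quartiles <- function(scores) {
  stopifnot(is.data.frame(scores), "intensity_per_cell_AU" %in% names(scores))
  x <- scores$intensity_per_cell_AU
  if (length(x) < 4) stop("quartile classification needs at least 4 regions")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lv <- c("low", "moderately low", "moderately high", "high")
  idx <- 1L + (x >= qs[1]) + (x >= qs[2]) + (x >= qs[3])
  scores$level <- factor(lv[idx], levels = lv, ordered = TRUE)
  attr(scores, "percentiles") <- stats::setNames(qs, c("p25", "p50", "p75"))
  scores
}
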