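#' Run the full per-cell disc quantification pipeline on one scene
#'
#' Chains every stage of the multiplex quantification on a (typically
#' simulated) image stack: train a DAPI+ area classifier and detect
#' individual nuclei inside it, expand nuclei into 2 um discs, train one
#' pixel classifier per marker channel and classify disc centroids, train
#' the high/low target-area classifier and subtract the per-ROI low-area
#' median from disc means, optionally re-detect one marker's cells from its
#' own staining (IBA1 mode, no expansion), normalize by the DAPI-disc upper
#' quartile, apply exclusion rules, and summarize.
#'
#' Classifier training annotations are sparse pixel samples drawn from the
#' scene's ground-truth staining masks, standing in for the manual brush
#' annotations used on real slides.  Set `use_truth_masks = TRUE` to bypass
#' the classifiers and use the ground-truth masks directly (fast path for
#' tests that exercise later stages).
#'
#' @param sim output of [generate_tissue_image()].
#' @param markers named character vector: marker name -> channel name in
#'   the stack.
#' @param iba1_marker optional marker name re-detected from its own
#'   staining instead of DAPI (detection area not expanded).
#' @param params a [detection_params()].
#' @param local_norm named numeric vector: marker name -> local
#'   normalization scale (um) for that marker's classifier.
#' @param roi optional [roi()]/logical mask; `NULL` = whole image.
#' @param subject,region identifiers stamped on the records.
#' @param exclusion_rules passed to [apply_exclusions()].
#' @param use_truth_masks bypass pixel classifiers with ground-truth masks.
#' @param ann_n annotation pixels sampled per class per classifier.
#' @param seed seed for annotation sampling and classifier init.
#' @return list: `records` (per-disc table), `summary`
#'   ([summarize_discs()] output), `low_median`, `nuclei`, `discs`,
#'   `marker_masks`, `high_mask`, `exclusions`.
#' @export
run_disc_pipeline <- function(sim, markers,
                              iba1_marker = NULL,
                              params = detection_params(),
                              local_norm = NULL,
                              roi = NULL, subject = "S1", region = "ROI",
                              exclusion_rules = list(),
                              use_truth_masks = FALSE,
                              ann_n = 1500, seed = 1) {
  stack <- sim$stack
  ps <- stack$pixel_size_um
  target <- stack$channels$target
  dapi <- stack$channels$DAPI
  dm <- dim(as_plane_matrix(dapi))

  # --- DAPI+ areas --------------------------------------------------------
  truth_dapi <- sim$masks$nuclei > 0
  if (use_truth_masks) {
    dapi_mask <- truth_dapi
  } else {
    cfg <- classifier_config(features = c("gaussian", "laplacian_of_gaussian",
                                          "gradient_magnitude"),
                             scales_um = c(0.5, 1, 2, 4),
                             min_object_um2 = 10, min_hole_um2 = 20,
                             pixel_size_um = ps, seed = seed)
    fe <- compute_features(dapi, cfg)
    ann <- sample_annotations(truth_dapi, ann_n, seed = seed)
    dapi_mask <- classify_pixels(train_pixel_classifier(fe, ann, cfg),
                                 fe)$positive
  }

  # --- nuclei and discs ---------------------------------------------------
  nuclei <- detect_cells(dapi, params, within = dapi_mask)
  discs <- expand_to_discs(nuclei, params$expansion_um, ps, roi = roi)
  records <- measure_discs(target, discs, source = "DAPI",
                           subject = subject, region = region)

  # --- marker masks and disc classification -------------------------------
  marker_masks <- list()
  for (mk in names(markers)) {
    ch <- markers[[mk]]
    truth_mk <- sim$masks$marker_positive[[ch]]
    if (is.null(truth_mk)) stop(sprintf("channel '%s' not in scene", ch))
    if (use_truth_masks) {
      marker_masks[[mk]] <- truth_mk
    } else {
      ln <- if (!is.null(local_norm) && mk %in% names(local_norm))
        local_norm[[mk]] else NULL
      cfg <- classifier_config(features = c("gaussian",
                                            "laplacian_of_gaussian"),
                               scales_um = c(0.5, 1, 2, 4),
                               local_normalization_scale_um = ln,
                               min_object_um2 = 10, min_hole_um2 = 20,
                               pixel_size_um = ps, seed = seed + 1)
      fe <- compute_features(stack$channels[[ch]], cfg)
      ann <- sample_annotations(truth_mk, ann_n, seed = seed + 1)
      marker_masks[[mk]] <- classify_pixels(
        train_pixel_classifier(fe, ann, cfg), fe)$positive
    }
  }
  records <- classify_discs(records, marker_masks)

  # --- IBA1-style re-detection (no expansion) -----------------------------
  if (!is.null(iba1_marker)) {
    ch <- markers[[iba1_marker]]
    lab2 <- detect_cells_iba1(stack$channels[[ch]], params,
                              iba1_mask = marker_masks[[iba1_marker]])
    rec2 <- measure_discs(target, lab2, source = "IBA1",
                          subject = subject, region = region)
    if (nrow(rec2) > 0) {
      rec2$disc_id <- rec2$disc_id + max(c(0L, records$disc_id))
      rec2 <- classify_discs(rec2, marker_masks)
      records <- rbind(records, rec2)
      attr(records, "markers") <- names(marker_masks)
    }
  }

  # --- diffuse correction -------------------------------------------------
  truth_high <- {
    pos_ids <- sim$truth$cell_id[sim$truth$true_target_mean > 0]
    matrix(sim$masks$soma %in% pos_ids, dm[1], dm[2])
  }
  if (use_truth_masks) {
    high_mask <- truth_high
  } else {
    cfg <- classifier_config(features = c("gaussian",
                                          "laplacian_of_gaussian",
                                          "weighted_std"),
                             scales_um = c(0.5, 1, 2, 4, 8),
                             local_normalization_scale_um = 32,
                             min_object_um2 = 0, min_hole_um2 = 0,
                             pixel_size_um = ps, seed = seed + 2)
    fe <- compute_features(target, cfg)
    ann <- sample_annotations(truth_high, ann_n, seed = seed + 2)
    high_mask <- classify_pixels(train_pixel_classifier(fe, ann, cfg),
                                 fe)$positive
  }
  dc <- diffuse_correction(target, roi, high_mask, records)
  records <- dc$records

  # --- normalization, exclusions, summary ---------------------------------
  records <- normalize_upper_quartile(records)
  ex <- apply_exclusions(records, exclusion_rules)
  summary <- summarize_discs(ex$records)
  list(records = records, summary = summary, low_median = dc$low_median,
       nuclei = nuclei, discs = discs, marker_masks = marker_masks,
       high_mask = high_mask, exclusions = ex)
}
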