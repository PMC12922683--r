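test_that("cell detection handles blanks, size bounds and planted fields", {
  p <- detection_params()
  blank <- image_plane(matrix(0, 200, 200), 0.5)
  expect_equal(max(detect_cells(blank, p)), 0)
  # empty `within` mask: zero detections, not an error
  expect_equal(max(detect_cells(blank, p, within = matrix(FALSE, 200, 200))),
               0)
  # a 150 um^2 blob (r ~ 6.9 um) exceeds max_area and is rejected
  big <- matrix(0, 200, 200)
  big[disc_mask(200, 200, 100, 100, 13.8)] <- 100
  p_nosplit <- detection_params(split_by_shape = FALSE)
  expect_equal(max(detect_cells(image_plane(big, 0.5), p_nosplit,
                                within = big > 0)), 0)

  # simulated field: >= 98% of planted nuclei detected, all areas in bounds
  sim <- small_scene()
  lab <- detect_cells(sim$stack$channels$DAPI, p,
                      within = sim$masks$nuclei > 0)
  n_planted <- nrow(sim$truth)
  expect_gte(max(lab), ceiling(0.98 * n_planted))
  areas <- attr(lab, "areas_um2")
  expect_true(all(areas >= 10 & areas <= 100))
})

test_that("disc expansion is Voronoi-constrained and matches a pixel oracle", {
  # single circular nucleus, radius 3 um at 0.5 um/px -> disc radius 5 um
  nuc <- matrix(0L, 60, 60)
  nuc[disc_mask(60, 60, 30, 30, 6)] <- 1L
  d <- expand_to_discs(nuc, 2, 0.5)
  ratio <- sum(d > 0) / sum(nuc > 0)
  expect_equal(ratio, 25 / 9, tolerance = 0.1)
  expect_true(all(d[nuc > 0] == 1))
  # expansion 0 is the identity
  expect_identical(expand_to_discs(nuc, 0, 0.5), nuc)

  # two nuclei: expanded labels disjoint, each expanded pixel joins its
  # nearest nucleus (brute-force per-pixel check)
  nuc2 <- matrix(0L, 60, 80)
  nuc2[disc_mask(60, 80, 30, 25, 5)] <- 1L
  nuc2[disc_mask(60, 80, 30, 36, 5)] <- 2L   # 3 um gap between masks
  d2 <- expand_to_discs(nuc2, 2, 0.5)
  p1 <- which(nuc2 == 1L); p2 <- which(nuc2 == 2L)
  r1 <- (p1 - 1) %% 60 + 1; c1 <- (p1 - 1) %/% 60 + 1
  r2 <- (p2 - 1) %% 60 + 1; c2 <- (p2 - 1) %/% 60 + 1
  for (px in which(d2 > 0 & nuc2 == 0L)) {
    i <- (px - 1) %% 60 + 1; j <- (px - 1) %/% 60 + 1
    d_1 <- sqrt(min((r1 - i)^2 + (c1 - j)^2))
    d_2 <- sqrt(min((r2 - i)^2 + (c2 - j)^2))
    expect_lte(min(d_1, d_2) * 0.5, 2 + 1e-9)
    if (d_1 < d_2) expect_equal(d2[px], 1L) else
      if (d_2 < d_1) expect_equal(d2[px], 2L)
  }
})

test_that("disc classification uses the centroid pixel and flags multi-positives", {
  nuc <- matrix(0L, 40, 40)
  nuc[disc_mask(40, 40, 12, 12, 4)] <- 1L
  nuc[disc_mask(40, 40, 28, 28, 4)] <- 2L
  rec <- measure_discs(matrix(1, 40, 40), nuc)
  m_in <- matrix(FALSE, 40, 40); m_in[12, 12] <- TRUE
  m_out <- matrix(FALSE, 40, 40); m_out[12, 13 + 4] <- TRUE # 1 px outside
  m_both <- matrix(TRUE, 40, 40)
  rc <- classify_discs(rec, list(A = m_in, B = m_out, C = m_both))
  expect_true(rc$A[rc$disc_id == 1])
  expect_false(rc$B[rc$disc_id == 1])
  expect_true(all(rc$C))
  expect_true(rc$multi_positive[rc$disc_id == 1])   # A and C
  expect_equal(rc$marker[rc$disc_id == 2], "C")
})

test_that("diffuse correction subtracts each ROI's own low-area median", {
  tg <- matrix(3, 50, 100)          # diffuse level 3 everywhere
  tg[, 51:100] <- 8                 # second ROI has diffuse 8
  high <- matrix(FALSE, 50, 100)
  high[21:30, 21:30] <- TRUE; tg[21:30, 21:30] <- 50
  high[21:30, 71:80] <- TRUE; tg[21:30, 71:80] <- 50
  roi1 <- matrix(FALSE, 50, 100); roi1[, 1:50] <- TRUE
  roi2 <- !roi1
  nuc <- matrix(0L, 50, 100)
  nuc[23:28, 23:28] <- 1L; nuc[23:28, 73:78] <- 2L
  rec <- measure_discs(tg, nuc)
  c1 <- diffuse_correction(tg, roi1, high, rec[1, ])
  c2 <- diffuse_correction(tg, roi2, high, rec[2, ])
  expect_equal(c1$low_median, 3)
  expect_equal(c2$low_median, 8)
  expect_equal(c1$records$diffuse_corrected_mean_AU, 47)
  expect_equal(c2$records$diffuse_corrected_mean_AU, 42)
  # zero diffuse: correction ~ 0, corrected ~ raw
  tg0 <- matrix(0, 50, 100); tg0[21:30, 21:30] <- 50
  nuc0 <- matrix(0L, 50, 100); nuc0[23:28, 23:28] <- 1L
  r0 <- diffuse_correction(tg0, NULL, high, measure_discs(tg0, nuc0))
  expect_equal(r0$low_median, 0)
  expect_equal(r0$records$diffuse_corrected_mean_AU,
               r0$records$raw_mean_AU)
  expect_error(diffuse_correction(tg, roi1, matrix(TRUE, 50, 100), rec),
               "empty")
})

test_that("upper-quartile normalization follows the stated percentile rule", {
  rec <- data.frame(disc_id = 1:4, subject = "S1", region = "R",
                    source = "DAPI",
                    diffuse_corrected_mean_AU = c(1, 2, 3, 4))
  out <- normalize_upper_quartile(rec)
  expect_equal(attr(out, "upper_quartiles")[[1]], 3.25)
  expect_equal(out$normalized_intensity[4], 4 / 3.25, tolerance = 1e-12)
  # all equal discs normalize to exactly 1
  rec_eq <- transform(rec, diffuse_corrected_mean_AU = 5)
  expect_true(all(normalize_upper_quartile(rec_eq)$normalized_intensity == 1))
  # scale invariance
  rec_sc <- transform(rec, diffuse_corrected_mean_AU =
                        7 * diffuse_corrected_mean_AU)
  expect_equal(normalize_upper_quartile(rec_sc)$normalized_intensity,
               out$normalized_intensity, tolerance = 1e-12)
  # IBA1 discs share the DAPI denominator
  rec_i <- rbind(rec, data.frame(disc_id = 5, subject = "S1", region = "R",
                                 source = "IBA1",
                                 diffuse_corrected_mean_AU = 6.5))
  out_i <- normalize_upper_quartile(rec_i)
  expect_equal(out_i$normalized_intensity[5], 2)
  # degenerate regions are rejected
  expect_error(normalize_upper_quartile(rec[1:3, ]), "fewer than 4")
  rec_neg <- transform(rec, diffuse_corrected_mean_AU = -(1:4))
  expect_error(normalize_upper_quartile(rec_neg), "non-positive")
})

test_that("exclusion rules remove the planted discs and report counts", {
  rec <- data.frame(disc_id = 1:6, subject = "S1",
                    region = c("SP", "SP", "CC", "CC", "SR", "SR"),
                    source = "DAPI", raw_mean_AU = 1,
                    ALDH1L1 = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                    CAMK2A = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    multi_positive = FALSE)
  attr(rec, "markers") <- c("ALDH1L1", "CAMK2A")
  ex <- apply_exclusions(rec, list(SP = "ALDH1L1", CC = "CAMK2A"))
  expect_equal(ex$removed$n, c(1, 2))
  expect_equal(nrow(ex$records), 3)
  expect_false(any(ex$records$region == "SP" & ex$records$ALDH1L1))
  # empty rulebook is the identity
  expect_equal(nrow(apply_exclusions(rec)$records), 6)
  expect_error(apply_exclusions(rec, list(SP = "NOPE")), "unknown marker")
})

test_that("summaries have one row per class with SEM rules honoured", {
  rec <- data.frame(disc_id = 1:3, subject = c("S1", "S1", "S2"),
                    region = "R", source = "DAPI",
                    marker = c("A", "A", "B"),
                    normalized_intensity = c(1, 3, 2))
  s <- summarize_discs(rec)
  a <- s[s$marker == "A", ]
  expect_equal(a$mean, 2); expect_equal(a$sem, 1); expect_equal(a$n, 2L)
  b <- s[s$marker == "B", ]
  expect_true(is.na(b$sem))
  # empty classes yield no row
  expect_false("C" %in% s$marker)
  expect_equal(nrow(s), 2)
})

test_that("end-to-end pipeline on the truth-mask path recovers planted ranks", {
  sim <- small_scene()
  res <- run_disc_pipeline(sim, c(neuron = "CAMK2A", glia = "ALDH1L1"),
                           use_truth_masks = TRUE, seed = 2)
  s <- res$summary
  expect_gt(s$mean[s$marker == "neuron"], s$mean[s$marker == "glia"])
  # diffuse level (5) + background (1) recovered by the low-area median
  expect_equal(res$low_median, 6, tolerance = 0.05)
  # corrected means recover planted values within 5%
  rec <- res$records
  for (cl in c("neuron", "glia")) {
    tru <- unique(sim$truth$true_target_mean[sim$truth$class_name == cl])
    got <- mean(rec$diffuse_corrected_mean_AU[rec$marker %in% cl])
    expect_equal(got, tru, tolerance = 0.05)
  }
  # discs never overlap and contain their nuclei
  expect_true(all(res$discs[res$nuclei > 0] == res$nuclei[res$nuclei > 0]))
})
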