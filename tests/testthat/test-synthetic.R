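test_that("empty scene gives a constant target channel at the background", {
  cfg <- tissue_sim_config(image_size_px = c(64, 64), cell_classes = NULL,
                           diffuse_level = 0, control_background = 0.7,
                           noise_frac = 0, seed = 3)
  sim <- generate_tissue_image(cfg)
  expect_equal(unique(as.vector(unclass(sim$stack$channels$target))), 0.7)
  expect_equal(nrow(sim$truth), 0)
})

test_that("identical seeds give bit-identical stacks; rows match counts", {
  cls <- data.frame(class_name = c("a", "b"),
                    marker_channel = c("CH1", "CH2"),
                    marker_pattern = c("somatic", "nuclear"),
                    true_target_mean = c(50, 5), count = c(7, 5))
  cfg <- tissue_sim_config(image_size_px = c(256, 256), cell_classes = cls,
                           puncta_count = 4, seed = 99)
  s1 <- generate_tissue_image(cfg)
  s2 <- generate_tissue_image(cfg)
  for (nm in names(s1$stack$channels))
    expect_identical(unclass(s1$stack$channels[[nm]]),
                     unclass(s2$stack$channels[[nm]]))
  # conservation: one ground-truth row per planted cell
  expect_equal(nrow(s1$truth), sum(cls$count))
  expect_equal(unname(table(s1$truth$class_name)[c("a", "b")]),
               c(7, 5), ignore_attr = TRUE)
  # centroids inside bounds
  expect_true(all(s1$truth$x_um > 0 & s1$truth$x_um < 128))
  expect_true(all(s1$truth$y_um > 0 & s1$truth$y_um < 128))
})

test_that("soma means recover the planted target means within 2%", {
  cls <- data.frame(class_name = c("neuron", "micro"),
                    marker_channel = c("CAMK2A", "IBA1"),
                    marker_pattern = "somatic",
                    true_target_mean = c(100, 5), count = c(50, 50))
  cfg <- tissue_sim_config(image_size_px = c(1000, 1000), cell_classes = cls,
                           nucleus_area_um2_range = c(30, 60), seed = 12)
  sim <- generate_tissue_image(cfg)
  tg <- unclass(sim$stack$channels$target)
  for (cl in c("neuron", "micro")) {
    ids <- sim$truth$cell_id[sim$truth$class_name == cl]
    mts <- vapply(ids, function(id) mean(tg[sim$masks$soma == id]), 0)
    tru <- sim$truth$true_target_mean[match(ids, sim$truth$cell_id)]
    expect_lt(max(abs(mts / tru - 1)), 0.02)
  }
  # polarized mode: signal concentrated on one side of the nucleus, so the
  # intensity-weighted centroid is displaced from the nucleus centroid
  id <- sim$truth$cell_id[sim$truth$class_name == "neuron"][1]
  px <- which(sim$masks$soma == id)
  w <- tg[px]
  rr <- (px - 1) %% 1000 + 1; cc <- (px - 1) %/% 1000 + 1
  shift_um <- sqrt((sum(w * rr) / sum(w) - sim$truth$y_um[id] / 0.5)^2 +
                   (sum(w * cc) / sum(w) - sim$truth$x_um[id] / 0.5)^2) * 0.5
  expect_gt(shift_um, 1)
})

test_that("over-dense scenes fail with an error naming the class", {
  cls <- data.frame(class_name = "packed", marker_channel = "CH1",
                    marker_pattern = "somatic", true_target_mean = 1,
                    count = 500)
  cfg <- tissue_sim_config(image_size_px = c(64, 64), cell_classes = cls,
                           seed = 1)
  expect_error(generate_tissue_image(cfg), "packed")
})

test_that("control image is background plus exactly the planted puncta", {
  cfg <- tissue_sim_config(image_size_px = c(256, 256), cell_classes = NULL,
                           control_background = 0.3, puncta_count = 0,
                           noise_frac = 0.02, seed = 5)
  ctl <- generate_control_image(cfg)
  expect_equal(mean(ctl), 0.3, tolerance = 0.01)
  cfg10 <- tissue_sim_config(image_size_px = c(256, 256), cell_classes = NULL,
                             control_background = 0.3, puncta_count = 10,
                             seed = 6)
  ctl10 <- generate_control_image(cfg10)
  comps <- label_components(unclass(ctl10) > 0.3 + 10, 8)
  expect_equal(max(comps), 10)
  expect_identical(unclass(generate_control_image(cfg10)), unclass(ctl10))
})

test_that("cluster matrices plant exact means, class order and determinism", {
  rb <- list(neuron = "Snap25x", immune = "Aif1")
  cfg <- cluster_sim_config(c(neuron = 1, immune = 1),
                            c(neuron = 1.0, immune = 0.01),
                            rb, noise_sd = 0, seed = 2)
  g <- generate_cluster_matrix(cfg)
  expect_equal(unname(g$matrix$expr[, "Igf2r"]), c(1.0, 0.01))
  # noisy matrices preserve the planted ordering of class means
  cfgn <- cluster_sim_config(c(neuron = 6, immune = 6),
                             c(neuron = 1.0, immune = 0.01),
                             rb, noise_sd = 0.05, seed = 3)
  gn <- generate_cluster_matrix(cfgn)
  mns <- tapply(gn$matrix$expr[, "Igf2r"], gn$labels, mean)
  expect_gt(mns["neuron"], mns["immune"])
  expect_identical(generate_cluster_matrix(cfgn)$matrix$expr,
                   gn$matrix$expr)
  # a class without markers is rejected
  expect_error(cluster_sim_config(c(a = 1), c(a = 1), list(a = character(0))),
               "marker")
})

test_that("vessel scenes draw adjacent but non-overlapping endothelial/mural rings", {
  cls <- data.frame(class_name = "muralcell", marker_channel = "PDGFRB",
                    marker_pattern = "vessel_ring", true_target_mean = 30,
                    count = 4, soma_expansion_um = 3,
                    inner_channel = "CD31")
  cfg <- tissue_sim_config(image_size_px = c(400, 400), cell_classes = cls,
                           noise_frac = 0, seed = 44)
  sim <- generate_tissue_image(cfg)
  inner <- sim$masks$marker_positive$CD31
  outer <- sim$masks$marker_positive$PDGFRB
  expect_true(any(inner)); expect_true(any(outer))
  # rings never overlap, but are adjacent: every inner-ring component lies
  # within 2 px of the outer ring
  expect_false(any(inner & outer))
  d_to_outer <- distance_transform(outer)$dist
  expect_lt(max(d_to_outer[inner]), 1.5 / 0.5 + 2)  # within the ring width
  # channels are adjacent, not colocalized
  m <- manders_coefficients(unclass(sim$stack$channels$CD31),
                            unclass(sim$stack$channels$PDGFRB))
  expect_lt(m$M1, 0.05)
})
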