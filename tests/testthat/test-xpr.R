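make_sim_matrix <- function(noise_sd = 0, seed = 1, n_per = 3) {
  rb <- list(neuron = "Snap25x", mural = c("Pdgfrb", "Acta2"),
             ependymal = c("Ttr", "Foxj1"), astrocytes = "Aldh1l1",
             immune = "Aif1")
  cfg <- cluster_sim_config(
    stats::setNames(rep(n_per, 5), names(rb)),
    c(neuron = 1.0, mural = 0.5, ependymal = 0.3, astrocytes = 0.1,
      immune = 0.01),
    rb, noise_sd = noise_sd, seed = seed)
  generate_cluster_matrix(cfg)
}

test_that("population filtering is exact bookkeeping, never silent", {
  g <- make_sim_matrix()
  cm <- g$matrix
  cm$meta$annotation[1:3] <- "Pituitary"
  cm <- cluster_matrix(cm$expr, cm$meta)
  f <- filter_populations(cm, "Pituitary")
  expect_equal(unname(attr(f, "n_removed")["Pituitary"]), 3L)
  expect_equal(nrow(f$expr), nrow(cm$expr) - 3)
  # empty exclusion list is the identity
  f0 <- filter_populations(cm)
  expect_identical(f0$expr, cm$expr)
  # unresolvable names warn and are reported
  expect_warning(fu <- filter_populations(cm, "Granulocyte"), "Granulocyte")
  expect_equal(attr(fu, "unresolved"), "Granulocyte")
  # excluding everything leaves an explicitly empty matrix
  suppressWarnings({
    fe <- filter_populations(cm, unique(cm$meta$annotation))
  })
  expect_true(attr(fe, "empty"))
})

test_that("marker scoring assigns planted classes and canonical examples", {
  g <- make_sim_matrix(noise_sd = 0)
  rb <- list(neuron = "Snap25x", mural = c("Pdgfrb", "Acta2"),
             ependymal = c("Ttr", "Foxj1"), astrocytes = "Aldh1l1",
             immune = "Aif1")
  asg <- assign_classes(g$matrix, rb)
  expect_equal(asg$class, g$labels)          # 100% recovery at zero noise
  # a cluster expressing only Aif1 high maps to the immune class under the
  # default rulebook
  genes <- c("Aif1", "Aldh1l1", "Chat", "Gad1", "Slc17a7")
  expr <- matrix(0, 2, 5, dimnames = list(c("c1", "c2"), genes))
  expr["c1", "Aif1"] <- 2
  cm <- cluster_matrix(expr)
  asg2 <- suppressWarnings(assign_classes(cm, default_marker_rulebook()))
  expect_equal(asg2$class[asg2$cluster == "c1"], "immune")
  # all-zero marker expression -> unassigned
  expect_equal(asg2$class[asg2$cluster == "c2"], "unassigned")
  # equal Gad1 and Chat: priority order picks cholinergic, flagged ambiguous
  expr["c2", c("Gad1", "Chat")] <- 1
  asg3 <- suppressWarnings(assign_classes(cluster_matrix(expr),
                                          default_marker_rulebook()))
  expect_equal(asg3$class[asg3$cluster == "c2"], "cholinergic")
  expect_true(asg3$ambiguous[asg3$cluster == "c2"])
  # manual overrides are explicit
  asg4 <- suppressWarnings(assign_classes(cluster_matrix(expr),
                                          default_marker_rulebook(),
                                          overrides = c(c2 = "other neurons")))
  expect_equal(asg4$class[asg4$cluster == "c2"], "other neurons")
})

test_that("class summaries are unweighted with SEM and rank rules", {
  g <- make_sim_matrix(noise_sd = 0)
  s <- class_summary(g$matrix, g$labels, "Igf2r")
  expect_equal(s$class_name[s$rank == 1], "neuron")
  expect_equal(s$class_name[order(s$rank)],
               c("neuron", "mural", "ependymal", "astrocytes", "immune"))
  expect_true(all(sort(s$rank) == 1:5))
  # mean/SEM arithmetic and the singleton rule
  expr <- matrix(c(1, 3, 5), 3, 1, dimnames = list(paste0("c", 1:3), "G"))
  s2 <- class_summary(cluster_matrix(expr), c("x", "x", "y"), "G")
  expect_equal(s2$mean[s2$class_name == "x"], 2)
  expect_equal(s2$sem[s2$class_name == "x"], 1)
  expect_true(is.na(s2$sem[s2$class_name == "y"]))
  expect_error(class_summary(g$matrix, g$labels, "Nope"), "absent")
  # invariant to cluster order
  perm <- sample(nrow(g$matrix$expr))
  cmp <- cluster_matrix(g$matrix$expr[perm, ], g$matrix$meta[perm, ])
  sp <- class_summary(cmp, g$labels[perm], "Igf2r")
  expect_equal(sp[order(sp$class_name), c("mean", "sem")],
               s[order(s$class_name), c("mean", "sem")],
               ignore_attr = TRUE)
})

test_that("filtering commutes with assignment and summarizing", {
  g <- make_sim_matrix(noise_sd = 0.02, seed = 8)
  cm <- g$matrix
  rb <- list(neuron = "Snap25x", mural = c("Pdgfrb", "Acta2"),
             ependymal = c("Ttr", "Foxj1"), astrocytes = "Aldh1l1",
             immune = "Aif1")
  drop_name <- cm$meta$annotation[1]
  # filter first
  f <- suppressWarnings(filter_populations(cm, drop_name))
  s1 <- class_summary(f, assign_classes(f, rb), "Igf2r")
  # assign first, then drop the same cluster
  asg <- assign_classes(cm, rb)
  keep <- cm$meta$annotation != drop_name
  cm2 <- cluster_matrix(cm$expr[keep, ], cm$meta[keep, ])
  s2 <- class_summary(cm2, asg$class[keep], "Igf2r")
  expect_equal(s1, s2)
})

test_that("rank concordance matches the closed-form Spearman oracle", {
  g <- make_sim_matrix(noise_sd = 0)
  s <- class_summary(g$matrix, g$labels, "Igf2r")
  # identical rankings give exactly 1
  rc <- rank_consistency(list(d1 = s, d2 = s))
  expect_equal(rc$pairs$spearman, 1)
  expect_true(all(rc$rank_spread == 0))
  # exactly reversed rankings of 5 classes give -1
  s_rev <- s; s_rev$mean <- -s$mean
  rc2 <- rank_consistency(list(d1 = s, d2 = s_rev))
  expect_equal(rc2$pairs$spearman, -1)
  # random permutations over 8 classes: match 1 - 6*sum(d^2)/(n(n^2-1))
  set.seed(33)
  cls <- letters[1:8]
  for (rep in 1:5) {
    sA <- data.frame(class_name = cls, mean = sample(8))
    sB <- data.frame(class_name = cls, mean = sample(8))
    rA <- rank(-sA$mean); rB <- rank(-sB$mean)
    want <- 1 - 6 * sum((rA - rB)^2) / (8 * (64 - 1))
    got <- rank_consistency(list(a = sA, b = sB))$pairs$spearman
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(rank_consistency(list(a = s[1:2, ], b = s[1:2, ])),
               "three shared")
})
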