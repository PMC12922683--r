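# independent least-squares oracle: F statistics from explicit design-matrix
# projections
proj_rss <- function(X, y) {
  q <- qr(X)
  sum(qr.resid(q, y)^2)
}

oneway_F_oracle <- function(values, groups) {
  g <- factor(groups)
  X1 <- stats::model.matrix(~g)
  X0 <- stats::model.matrix(~1, data.frame(values))
  rss1 <- proj_rss(X1, values); rss0 <- proj_rss(X0, values)
  df1 <- nlevels(g) - 1; df2 <- length(values) - nlevels(g)
  ((rss0 - rss1) / df1) / (rss1 / df2)
}

test_that("one-way ANOVA matches explicit sums-of-squares arithmetic", {
  d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
                  value = c(1, 2, 3, 2, 4, 6, 10, 11, 12))
  r <- oneway_anova_tukey(d)
  expect_equal(r$anova$F[1], oneway_F_oracle(d$value, d$group),
               tolerance = 1e-10)
  # permutation and shift invariance
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  expect_equal(oneway_anova_tukey(d2)$anova$F[1], r$anova$F[1],
               tolerance = 1e-12)
  d3 <- transform(d, value = value + 100)
  expect_equal(oneway_anova_tukey(d3)$anova$F[1], r$anova$F[1],
               tolerance = 1e-10)
  # identical group means with nonzero spread: F = 0, p = 1
  d0 <- data.frame(group = rep(c("a", "b"), each = 3),
                   value = c(1, 2, 3, 3, 2, 1))
  r0 <- oneway_anova_tukey(d0)
  expect_equal(r0$anova$F[1], 0)
  expect_equal(r0$anova$p[1], 1)
})

test_that("two-group Tukey p equals the equal-variance two-sample test p", {
  set.seed(42)
  d <- data.frame(group = rep(c("x", "y"), c(6, 8)),
                  value = c(rnorm(6), rnorm(8, 1)))
  r <- oneway_anova_tukey(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(r$tukey$p_adj, tt$p.value, tolerance = 1e-8)
  # Tukey adjusted p is never below the plain pairwise p
  set.seed(7)
  d5 <- data.frame(group = rep(letters[1:5], each = 4), value = rnorm(20))
  r5 <- oneway_anova_tukey(d5)
  for (i in seq_len(nrow(r5$tukey))) {
    gs <- strsplit(r5$tukey$contrast[i], "-")[[1]]
    sub <- d5[d5$group %in% gs, ]
    p2 <- t.test(value ~ group, data = sub, var.equal = TRUE)$p.value
    expect_gte(r5$tukey$p_adj[i], p2 - 1e-10)
  }
})

test_that("blocked two-way ANOVA matches a projection-based oracle", {
  set.seed(13)
  for (rep in 1:6) {
    nA <- sample(2:4, 1); nB <- sample(2:3, 1); nS <- sample(3:5, 1)
    d <- expand.grid(A = factor(seq_len(nA)), B = factor(seq_len(nB)),
                     S = factor(seq_len(nS)))
    d$value <- rnorm(nrow(d))
    r <- twoway_anova_blocked(d, value = "value", marker = "A",
                              region = "B", block = "S", tukey = FALSE)
    # oracle: Type II SS by explicit QR projections
    y <- d$value
    X <- function(f) stats::model.matrix(f, d)
    rss_full <- proj_rss(X(~ S + A * B), y)
    df_res <- nrow(d) - (nS - 1) - (nA - 1) - (nB - 1) -
      (nA - 1) * (nB - 1) - 1
    mse <- rss_full / df_res
    ssA <- proj_rss(X(~ S + B), y) - proj_rss(X(~ S + A + B), y)
    ssB <- proj_rss(X(~ S + A), y) - proj_rss(X(~ S + A + B), y)
    ssAB <- proj_rss(X(~ S + A + B), y) - rss_full
    want_F <- c(ssA / (nA - 1), ssB / (nB - 1),
                ssAB / ((nA - 1) * (nB - 1))) / mse
    expect_equal(r$anova$F[2:4], want_F, tolerance = 1e-8)
  }
})

test_that("with no block variance the blocked fit collapses to the unblocked one", {
  # every block sees identical data, so the block SS is exactly zero
  base <- expand.grid(A = factor(1:3), B = factor(1:2))
  base$mu <- c(1, 2, 3, 2, 3, 5)
  d <- do.call(rbind, lapply(1:4, function(s) transform(base, S = s)))
  d$value <- d$mu + rep(c(0.3, -0.3, 0.1, -0.1), each = 6)[seq_len(nrow(d))]
  # make replicate deviations identical across blocks
  d$value <- d$mu + rep(c(0.3, -0.3, 0.1, -0.1, 0.2, -0.2), times = 4)
  r <- twoway_anova_blocked(d, marker = "A", region = "B", block = "S",
                            tukey = FALSE)
  expect_lt(r$anova$sumsq[r$anova$term == "S"], 1e-20)
  # with the block explaining nothing, the treatment sums of squares equal
  # the unblocked two-way decomposition exactly
  ssA_nb <- sum(qr.resid(qr(stats::model.matrix(~B, d)), d$value)^2) -
    sum(qr.resid(qr(stats::model.matrix(~A + B, d)), d$value)^2)
  expect_equal(r$anova$sumsq[r$anova$term == "A"], ssA_nb, tolerance = 1e-10)
})

test_that("aliased designs are rejected", {
  d <- expand.grid(A = factor(1:2), S = factor(1:4))
  d$B <- d$S   # block confounded with region
  d$value <- rnorm(nrow(d))
  expect_error(twoway_anova_blocked(d, marker = "A", region = "B",
                                    block = "S"), "alias")
})

test_that("a planted marker effect is detected and a null region stays null", {
  set.seed(99)
  n_rep <- 100
  pA <- pB <- numeric(n_rep)
  d0 <- expand.grid(A = factor(1:3), B = factor(1:2), S = factor(1:5))
  eff <- c(0, 0.8, 1.6)[as.integer(d0$A)]
  for (i in seq_len(n_rep)) {
    d0$value <- eff + rnorm(nrow(d0), 0, 0.8) +
      rep(rnorm(5, 0, 0.3), each = 6)[as.integer(d0$S)]
    r <- twoway_anova_blocked(d0, marker = "A", region = "B", block = "S",
                              tukey = FALSE)
    pA[i] <- r$anova$p[2]; pB[i] <- r$anova$p[3]
  }
  expect_gte(mean(pA < 0.05), 0.8)            # power on the planted effect
  expect_lt(abs(mean(pB < 0.05) - 0.05), 0.07) # null region ~ nominal level
})

test_that("assumption diagnostics match their oracles and degrade gracefully", {
  # Mauchly with two conditions: sphericity holds trivially
  w2 <- assumption_checks(wide = matrix(rnorm(20), 10, 2))
  expect_equal(w2$mauchly$W, 1); expect_equal(w2$mauchly$p, 1)
  # Levene F = 0 on a balanced set with identical per-group deviations
  v <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  lv <- assumption_checks(values = v, groups = g)
  expect_equal(lv$levene$F, 0)
  # insufficient data: that test missing, others still run
  part <- assumption_checks(residuals = rnorm(10), wide = NULL)
  expect_false(is.na(part$shapiro$W))
  expect_true(is.na(part$levene$F))
  expect_true(is.na(part$mauchly$W))
  # Mauchly W for k = 3 equals the determinant formula computed directly
  set.seed(2)
  wide <- matrix(rnorm(45), 15, 3) %*% diag(c(1, 1.5, 2))
  mk <- assumption_checks(wide = wide)$mauchly
  C <- qr.Q(qr(stats::contr.helmert(3)))
  A <- crossprod(scale(wide %*% C, center = TRUE, scale = FALSE))
  W_direct <- det(A) / (sum(diag(A)) / 2)^2
  expect_equal(mk$W, W_direct, tolerance = 1e-12)
})

test_that("Shapiro-Wilk W matches an independently coded coefficient oracle", {
  # Royston's published approximation to the Shapiro-Wilk coefficients,
  # implemented here from the printed polynomials (independent of
  # stats::shapiro.test's compiled code)
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195) / 10
  n <- length(x)
  m <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  c_vec <- m / sqrt(sum(m^2))
  u <- 1 / sqrt(n)
  a <- m
  a_n <- c_vec[n] + u * (0.221157 + u * (-0.147981 + u * (-2.071190 +
         u * (4.434685 + u * (-2.706056)))))
  a_n1 <- c_vec[n - 1] + u * (0.042981 + u * (-0.293762 + u * (-1.752461 +
          u * (5.682633 + u * (-3.582633)))))
  phi <- (sum(m^2) - 2 * m[n]^2 - 2 * m[n - 1]^2) /
    (1 - 2 * a_n^2 - 2 * a_n1^2)
  a <- m / sqrt(phi)
  a[n] <- a_n; a[1] <- -a_n
  a[n - 1] <- a_n1; a[2] <- -a_n1
  xs <- sort(x)
  W_oracle <- sum(a * xs)^2 / sum((xs - mean(xs))^2)
  got <- assumption_checks(residuals = x)$shapiro
  expect_equal(got$W, W_oracle, tolerance = 1e-6)
})
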