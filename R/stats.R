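#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' Classical fixed-effects decomposition; Tukey's honestly-significant
#' -difference p-values come from the studentized range distribution with
#' the Tukey--Kramer standard error for unbalanced groups.  With two groups
#' the Tukey-adjusted p equals the equal-variance two-sample test p.
#'
#' @param data data frame with one observation per row.
#' @param value,group column names of the response and the grouping factor.
#' @param tukey compute the pairwise table (disable for speed in
#'   simulations).
#' @param conf_level confidence level of the Tukey intervals.
#' @return list of class `anova_result`: `anova` (term table with df, sum of
#'   squares, F, p), `tukey` (pairwise differences, adjusted p, bounds),
#'   `residuals`.
#' @export
oneway_anova_tukey <- function(data, value = "value", group = "group",
                               tukey = TRUE, conf_level = 0.95) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  x <- data[[value]]
  g <- factor(data[[group]])
  stopifnot(all(is.finite(x)))
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups")
  n_i <- tabulate(g)
  if (any(n_i < 1)) stop("every group needs at least one observation")
  N <- length(x)
  m_i <- tapply(x, g, mean)
  m <- mean(x)
  ssb <- sum(n_i * (m_i - m)^2)
  resid <- x - m_i[as.integer(g)]
  ssw <- sum(resid^2)
  dfb <- k - 1; dfw <- N - k
  if (dfw < 1) stop("no residual degrees of freedom")
  mse <- ssw / dfw
  f <- if (mse > 0) (ssb / dfb) / mse else ifelse(ssb > 0, Inf, NaN)
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  tab <- data.frame(term = c(group, "Residuals"),
                    df = c(dfb, dfw), sumsq = c(ssb, ssw),
                    F = c(f, NA), p = c(p, NA),
                    stringsAsFactors = FALSE)
  tk <- NULL
  if (tukey) {
    if (any(n_i < 2))
      stop("Tukey post hoc tests need at least two observations per group")
    tk <- tukey_table(m_i, n_i, mse, dfw, k, levels(g), conf_level)
  }
  structure(list(anova = tab, tukey = tk, residuals = unname(resid)),
            class = "anova_result")
}

tukey_table <- function(means, ns, mse, df, k, lev, conf_level,
                        prefix = NULL) {
  pairs <- utils::combn(length(means), 2)
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  qstat <- abs(diff) / se
  p_adj <- stats::ptukey(qstat, k, df, lower.tail = FALSE)
  qc <- stats::qtukey(conf_level, k, df)
  out <- data.frame(
    contrast = paste(lev[pairs[2, ]], lev[pairs[1, ]], sep = "-"),
    diff = unname(diff), lwr = unname(diff - qc * se),
    upr = unname(diff + qc * se), p_adj = unname(p_adj),
    stringsAsFactors = FALSE)
  if (!is.null(prefix)) out <- cbind(prefix, out)
  out
}

rss_of <- function(formula, data) stats::deviance(stats::lm(formula, data))

#' Blocked two-way ANOVA with Tukey post hoc tests
#'
#' Fixed-effects fit of `value ~ block + A * B` with an additive block
#' (subject) term, factorial factors A (marker) and B (region) and their
#' interaction, a single residual stratum, and Type II sums of squares by
#' default (Type I and III available).  Tukey--Kramer comparisons of marker
#' cell means are computed within each region.
#'
#' @param data data frame of replicate-level values.
#' @param value,marker,region,block column names.
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @param tukey,conf_level as in [oneway_anova_tukey()].
#' @return `anova_result` list; the Tukey table gains a `region` column.
#' @export
twoway_anova_blocked <- function(data, value = "value", marker = "marker",
                                 region = "region", block = "subject",
                                 ss_type = c("II", "I", "III"),
                                 tukey = TRUE, conf_level = 0.95) {
  ss_type <- match.arg(ss_type)
  stopifnot(all(c(value, marker, region, block) %in% names(data)))
  d <- data.frame(y = data[[value]], A = factor(data[[marker]]),
                  B = factor(data[[region]]), S = factor(data[[block]]))
  stopifnot(all(is.finite(d$y)))
  full <- stats::lm(y ~ S + A * B, data = d)
  if (any(is.na(stats::coef(full))))
    stop("aliased design: the block factor is confounded with a treatment factor")
  df_res <- stats::df.residual(full)
  if (df_res < 1) stop("design leaves no residual degrees of freedom")
  rss_full <- stats::deviance(full)
  mse <- rss_full / df_res
  dfA <- nlevels(d$A) - 1; dfB <- nlevels(d$B) - 1
  dfAB <- dfA * dfB; dfS <- nlevels(d$S) - 1
  if (ss_type == "I") {
    a1 <- stats::anova(full)
    ss <- a1[c("S", "A", "B", "A:B"), "Sum Sq"]
  } else if (ss_type == "II") {
    ss <- c(
      S = rss_of(y ~ A * B, d) - rss_of(y ~ S + A * B, d),
      A = rss_of(y ~ S + B, d) - rss_of(y ~ S + A + B, d),
      B = rss_of(y ~ S + A, d) - rss_of(y ~ S + A + B, d),
      `A:B` = rss_of(y ~ S + A + B, d) - rss_full)
  } else { # Type III with sum-to-zero contrasts
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op), add = TRUE)
    f3 <- stats::lm(y ~ S + A * B, data = d)
    X <- stats::model.matrix(f3)
    asn <- attr(X, "assign") # 0 intercept, 1 S, 2 A, 3 B, 4 A:B
    drop_ss <- function(term_id) {
      Xr <- X[, asn != term_id, drop = FALSE]
      stats::deviance(stats::lm.fit(Xr, d$y)) - stats::deviance(f3)
    }
    ss <- c(S = drop_ss(1), A = drop_ss(2), B = drop_ss(3),
            `A:B` = drop_ss(4))
  }
  dfs <- c(dfS, dfA, dfB, dfAB)
  fs <- (ss / dfs) / mse
  ps <- stats::pf(fs, dfs, df_res, lower.tail = FALSE)
  tab <- data.frame(term = c(block, marker, region,
                             paste(marker, region, sep = ":"), "Residuals"),
                    df = c(dfs, df_res), sumsq = c(unname(ss), rss_full),
                    F = c(unname(fs), NA), p = c(unname(ps), NA),
                    stringsAsFactors = FALSE)
  tk <- NULL
  if (tukey) {
    kA <- nlevels(d$A)
    tk <- do.call(rbind, lapply(levels(d$B), function(b) {
      sub <- d[d$B == b, ]
      mns <- tapply(sub$y, sub$A, mean)
      ns <- tabulate(sub$A, nbins = kA)
      keep <- !is.na(mns) & ns >= 1
      if (sum(keep) < 2) return(NULL)
      tukey_table(mns[keep], ns[keep], mse, df_res, sum(keep),
                  names(mns)[keep], conf_level,
                  prefix = data.frame(region = b, stringsAsFactors = FALSE))
    }))
  }
  structure(list(anova = tab, tukey = tk,
                 residuals = unname(stats::residuals(full))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$anova, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("\nTukey post hoc:\n")
    print(utils::head(x$tukey, 20), row.names = FALSE)
    if (nrow(x$tukey) > 20) cat(sprintf("... %d rows\n", nrow(x$tukey)))
  }
  invisible(x)
}

#' ANOVA assumption diagnostics
#'
#' Shapiro--Wilk normality test on residuals, Levene's test (centred at the
#' group mean) for homogeneity of variance, and Mauchly's test of
#' sphericity on orthonormal contrasts of a within-subject
#' (subject x condition) matrix.  Tests with insufficient data are reported
#' as missing; the others still run.  With two within-subject conditions
#' sphericity holds trivially (W = 1, p = 1).
#'
#' @param residuals numeric residuals (Shapiro--Wilk; needs >= 3).
#' @param values,groups observations and grouping for Levene's test
#'   (needs >= 2 groups).
#' @param wide numeric subject x condition matrix for Mauchly's test
#'   (needs >= 2 conditions).
#' @return list of class `assumption_checks` with elements `shapiro`
#'   (`W`, `p`), `levene` (`F`, `df1`, `df2`, `p`) and `mauchly`
#'   (`W`, `chisq`, `df`, `p`); unavailable entries are `NA`.
#' @export
assumption_checks <- function(residuals = NULL, values = NULL,
                              groups = NULL, wide = NULL) {
  sw <- list(W = NA_real_, p = NA_real_)
  if (!is.null(residuals) && sum(is.finite(residuals)) >= 3 &&
      stats::sd(residuals) > 0) {
    t <- stats::shapiro.test(residuals)
    sw <- list(W = unname(t$statistic), p = t$p.value)
  }
  lv <- list(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_)
  if (!is.null(values) && !is.null(groups)) {
    g <- factor(groups)
    if (nlevels(g) >= 2 && length(values) - nlevels(g) >= 1) {
      z <- abs(values - tapply(values, g, mean)[as.integer(g)])
      k <- nlevels(g); N <- length(z)
      mz_i <- tapply(z, g, mean); mz <- mean(z)
      n_i <- tabulate(g)
      ssb <- sum(n_i * (mz_i - mz)^2)
      ssw <- sum((z - mz_i[as.integer(g)])^2)
      f <- if (ssw > 0) (ssb / (k - 1)) / (ssw / (N - k)) else
        ifelse(ssb > 0, Inf, 0)
      lv <- list(F = f, df1 = k - 1, df2 = N - k,
                 p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
    }
  }
  mc <- list(W = NA_real_, chisq = NA_real_, df = NA_real_, p = NA_real_)
  if (!is.null(wide)) {
    wide <- as.matrix(wide)
    k <- ncol(wide); n <- nrow(wide)
    if (k >= 2 && n > k) {
      if (k == 2) {
        mc <- list(W = 1, chisq = 0, df = 0, p = 1)
      } else {
        C <- qr.Q(qr(stats::contr.helmert(k)))  # orthonormal contrasts
        M <- wide %*% C
        Mc <- sweep(M, 2, colMeans(M))
        A <- crossprod(Mc)
        pp <- k - 1
        W <- det(A) / (sum(diag(A)) / pp)^pp
        dfm <- pp * (pp + 1) / 2 - 1
        chisq <- -(n - 1 - (2 * pp^2 + pp + 2) / (6 * pp)) * log(W)
        mc <- list(W = W, chisq = chisq, df = dfm,
                   p = stats::pchisq(chisq, dfm, lower.tail = FALSE))
      }
    }
  }
  structure(list(shapiro = sw, levene = lv, mauchly = mc),
            class = "assumption_checks")
}

#' @export
print.assumption_checks <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, p = %.4g\n", x$shapiro$W,
              x$shapiro$p))
  cat(sprintf("Levene (center = mean): F(%g, %g) = %.4f, p = %.4g\n",
              x$levene$df1, x$levene$df2, x$levene$F, x$levene$p))
  cat(sprintf("Mauchly: W = %.4f, chisq(%g) = %.4f, p = %.4g\n",
              x$mauchly$W, x$mauchly$df, x$mauchly$chisq, x$mauchly$p))
  invisible(x)
}
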