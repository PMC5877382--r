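#' Agreement statistics between two measurement systems
#'
#' Validation statistics for paired per-stride measurements from two systems
#' that may both carry error: Bland-Altman bias and 95% limits of agreement
#' (with confidence intervals that account for repeated strides per subject),
#' intra-class correlation from a subject-grouped random-intercept model, and
#' per-sample residual summaries for synchronized signals.
#'
#' @name agreement_stats
NULL

#' Paired per-stride measurements
#'
#' @param value_a,value_b Measurements of the same quantity from systems A
#'   and B, same units.
#' @param subject Grouping label (e.g. horse id).
#' @param trial Trial label within subject.
#' @param stride Stride index within trial.
#' @return Data frame of class `paired_measurements`. Incomplete pairs are
#'   dropped with a warning.
#' @export
paired_measurements <- function(value_a, value_b, subject = 1L, trial = 1L,
                                stride = seq_along(value_a)) {
  df <- data.frame(value_a = value_a, value_b = value_b,
                   subject = as.character(subject), trial = as.character(trial),
                   stride = stride)
  bad <- !stats::complete.cases(df[, c("value_a", "value_b")])
  if (any(bad)) {
    warning(sprintf("dropping %d incomplete pair(s)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  class(df) <- c("paired_measurements", "data.frame")
  df
}

#' Residual statistics between two synchronized signals
#'
#' @param sig_a,sig_b Single-channel `gait_ts` (or plain numeric vectors) of
#'   equal length; gap samples are excluded pairwise.
#' @return List with `rmse`, `mean_residual`, `sd_residual` of the per-sample
#'   residual `a - b`, and `n` valid samples.
#' @export
residual_stats <- function(sig_a, sig_b) {
  get_x <- function(s) {
    if (inherits(s, "gait_ts")) { x <- s$data[, 1]; x[s$gap] <- NA; x }
    else as.numeric(s)
  }
  a <- get_x(sig_a); b <- get_x(sig_b)
  n <- min(length(a), length(b))
  r <- a[seq_len(n)] - b[seq_len(n)]
  r <- r[is.finite(r)]
  if (!length(r)) stop("no overlapping valid samples")
  list(rmse = sqrt(mean(r^2)), mean_residual = mean(r),
       sd_residual = stats::sd(r), n = length(r))
}

# variance components of x grouped by g via REML random-intercept fit
vc_random_intercept <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) {
    return(list(t00 = NA_real_, sigma2 = stats::var(x), nsub = nlevels(g)))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(x ~ 1 + (1 | g), REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(t00 = vc$vcov[vc$grp == "g"],
       sigma2 = vc$vcov[vc$grp == "Residual"],
       nsub = nlevels(g))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b` are plotted against pair means; the bias is the
#' mean difference and the limits of agreement (LOAs) lie 1.96 standard
#' deviations either side of it. With multiple strides per subject the
#' confidence intervals for bias and LOAs are computed from within- and
#' between-subject variance components (random-intercept REML fit,
#' Satterthwaite degrees of freedom, MOVER interval combination); with a
#' single subject the naive Bland-Altman intervals are used with a warning.
#' At `level = "trial_mean"` the pairs are averaged within each
#' subject-trial before analysis.
#'
#' @param pm A [paired_measurements()].
#' @param level `"per_stride"` or `"trial_mean"`.
#' @param conf Confidence level for the CIs.
#' @param loa_mult LOA multiplier (1.96 for 95% limits).
#' @return Object of class `ba_report`.
#' @export
bland_altman <- function(pm, level = c("per_stride", "trial_mean"),
                         conf = 0.95, loa_mult = 1.96) {
  stopifnot(inherits(pm, "paired_measurements"))
  level <- match.arg(level)
  if (level == "trial_mean") {
    key <- interaction(pm$subject, pm$trial, drop = TRUE)
    a <- tapply(pm$value_a, key, mean)
    b <- tapply(pm$value_b, key, mean)
    subj <- tapply(pm$subject, key, function(s) s[1])
    if (length(a) < 3) stop("trial_mean analysis needs at least 3 trials")
  } else {
    a <- pm$value_a; b <- pm$value_b; subj <- pm$subject
    if (length(a) < 3) stop("need at least 3 pairs")
  }
  d <- as.numeric(a - b)
  m <- as.numeric((a + b) / 2)
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  loa_u <- bias + loa_mult * s
  loa_l <- bias - loa_mult * s
  nsub <- length(unique(subj))
  alpha <- 1 - conf
  if (nsub >= 2 && any(table(subj) >= 2)) {
    vc <- vc_random_intercept(d, subj)
    t00 <- max(0, vc$t00); s2 <- vc$sigma2
    se_bias <- sqrt(t00 / nsub + s2 / n)
    df_b <- nsub - 1
    # Satterthwaite effective df for the total variance t00 + s2
    df_w <- max(n - nsub, 1)
    tot <- t00 + s2
    nu <- if (tot > 0 && (t00 > 0 || s2 > 0)) {
      tot^2 / (ifelse(t00 > 0, t00^2 / df_b, 0) + s2^2 / df_w)
    } else df_w
  } else {
    if (nsub < 2) {
      warning("single subject: using naive Bland-Altman confidence intervals")
    }  # one value per subject: components are inseparable, use the naive form
    se_bias <- s / sqrt(n)
    df_b <- n - 1
    nu <- n - 1
  }
  tq <- stats::qt(1 - alpha / 2, df_b)
  ci_bias <- bias + c(-1, 1) * tq * se_bias
  # CI for the SD via the chi-square distribution at nu effective df
  s_lo <- s * sqrt(nu / stats::qchisq(1 - alpha / 2, nu))
  s_hi <- s * sqrt(nu / stats::qchisq(alpha / 2, nu))
  # MOVER combination for bias + loa_mult * s
  ci_loa_u <- c(loa_u - sqrt((bias - ci_bias[1])^2 + loa_mult^2 * (s - s_lo)^2),
                loa_u + sqrt((ci_bias[2] - bias)^2 + loa_mult^2 * (s_hi - s)^2))
  ci_loa_l <- c(loa_l - sqrt((bias - ci_bias[1])^2 + loa_mult^2 * (s_hi - s)^2),
                loa_l + sqrt((ci_bias[2] - bias)^2 + loa_mult^2 * (s - s_lo)^2))
  slope <- if (stats::var(m) > 0) unname(stats::coef(stats::lm(d ~ m))[2]) else NA_real_
  structure(list(
    bias = bias, sd_diff = s,
    loa_upper = loa_u, loa_lower = loa_l,
    loa_ci = list(bias = ci_bias, loa_upper = ci_loa_u, loa_lower = ci_loa_l),
    regression_slope = slope,
    n = n, n_subjects = nsub, level = level, conf = conf,
    differences = d, means = m
  ), class = "ba_report")
}

#' @exportS3Method base::print
print.ba_report <- function(x, ...) {
  cat(sprintf("<ba_report> (%s, n = %d, %d subject(s))\n", x$level, x$n, x$n_subjects))
  cat(sprintf("  bias %8.3f  [%.3f, %.3f]\n", x$bias, x$loa_ci$bias[1], x$loa_ci$bias[2]))
  cat(sprintf("  LOA  %8.3f .. %.3f (1.96 SD)\n", x$loa_lower, x$loa_upper))
  cat(sprintf("  slope of d on mean: %.4f\n", x$regression_slope))
  invisible(x)
}

#' Plot a Bland-Altman report
#'
#' Differences against pair means with bias, limits of agreement and the
#' trend regression line.
#'
#' @param x A `ba_report`.
#' @param ... Passed to [plot()].
#' @export
plot.ba_report <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of systems", ylab = "difference (A - B)",
       pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = x$bias, col = "black", lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "firebrick", lty = 2)
  if (is.finite(x$regression_slope)) {
    graphics::abline(stats::lm(x$differences ~ x$means), col = "gray40", lty = 3)
  }
  invisible(x)
}

#' Intra-class correlation from a random-intercept model
#'
#' Fits `value ~ 1 + (1 | subject)` by REML and reports
#' `ICC = t00 / (t00 + sigma^2 / nj)`, where `t00` is the between-subject
#' intercept variance, `sigma^2` the residual variance and `nj` the (mean)
#' group size. The ICC is clipped to `[0, 1]`.
#'
#' @param x A [paired_measurements()] or a numeric response vector.
#' @param ... Further arguments to methods.
#' @return Object of class `icc_report`: `t00`, `sigma2`, `nj`, `icc`,
#'   `n_subjects`, `mode`.
#' @export
icc_mixed <- function(x, ...) UseMethod("icc_mixed")

#' @rdname icc_mixed
#' @param subject Grouping labels (>= 2 subjects, >= 2 observations each).
#' @export
icc_mixed.default <- function(x, subject, ...) {
  g <- factor(subject)
  stopifnot(length(x) == length(g))
  if (nlevels(g) < 2) stop("need at least 2 subjects")
  if (min(table(g)) < 2) stop("need at least 2 observations per subject")
  if (stats::var(x) <= 0) stop("zero total variance; ICC undefined")
  vc <- vc_random_intercept(x, g)
  t00 <- max(0, vc$t00); s2 <- vc$sigma2
  nj <- mean(table(g))
  icc <- t00 / (t00 + s2 / nj)
  icc <- min(1, max(0, icc))
  structure(list(t00 = t00, sigma2 = s2, nj = nj, icc = icc,
                 n_subjects = nlevels(g), mode = "response"),
            class = "icc_report")
}

#' @rdname icc_mixed
#' @param mode `"raw"` stacks both systems' values as the response (the
#'   default; ICC then reflects the reproducibility of the measurement across
#'   systems within subjects); `"difference"` models the per-stride
#'   between-system differences.
#' @export
icc_mixed.paired_measurements <- function(x, mode = c("raw", "difference"), ...) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    val <- c(x$value_a, x$value_b)
    subj <- c(x$subject, x$subject)
  } else {
    val <- x$value_a - x$value_b
    subj <- x$subject
  }
  out <- icc_mixed.default(val, subj)
  out$mode <- mode
  out
}

#' @exportS3Method base::print
print.icc_report <- function(x, ...) {
  cat(sprintf("<icc_report> ICC = %.3f (t00 = %.4g, sigma2 = %.4g, nj = %.1f, %d subjects, mode = %s)\n",
              x$icc, x$t00, x$sigma2, x$nj, x$n_subjects, x$mode))
  invisible(x)
}
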