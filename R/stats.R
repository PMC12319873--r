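# Group-level statistics: multivariate outlier flagging, bootstrap CIs,
# circular means and mean-direction tests, and the ADI-BSI correlation.
#
# The circular routines implement the standard textbook formulas
# (Fisher 1993; Zar 1999): the one-sample test rejects when the null
# direction falls outside the confidence cone of the circular mean, and the
# two-sample Watson-Williams test uses the concentration-corrected F
# statistic.

#' Multivariate outlier detection by Mahalanobis distance
#'
#' Treats each subject's measurements as a point in d-dimensional space and
#' flags points whose squared Mahalanobis distance from the (estimated or
#' supplied) mean exceeds the upper `alpha` tail of a chi-squared
#' distribution with d degrees of freedom — i.e. points whose likelihood
#' under a multivariate normal model is below `alpha`.
#'
#' @param points subjects x dims numeric matrix (or data frame).
#' @param alpha tail probability threshold (default 0.01).
#' @param center,cov optional known mean vector and covariance matrix; by
#'   default both are estimated from the sample.
#' @return data frame of class `outlier_report` with `point_id`,
#'   `mahalanobis_sq`, `tail_prob`, `flagged`.
#' @export
mahalanobis_outliers <- function(points, alpha = 0.01, center = NULL,
                                 cov = NULL) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must be in (0, 0.5)", call. = FALSE)
  estimated <- is.null(center) || is.null(cov)
  if (estimated && nrow(points) <= d + 1L) {
    stop("need more subjects than dims + 1 to estimate the covariance", call. = FALSE)
  }
  center <- center %||% colMeans(points)
  cov <- cov %||% stats::cov(points)
  kappa_c <- kappa(cov)
  if (!all(is.finite(cov)) || kappa_c > 1e12) {
    stop("singular covariance (condition number ", format(kappa_c, digits = 3),
         ")", call. = FALSE)
  }
  d2 <- mahalanobis(points, center, cov)
  tail <- pchisq(d2, df = d, lower.tail = FALSE)
  structure(
    data.frame(point_id = seq_len(nrow(points)), mahalanobis_sq = d2,
               tail_prob = tail, flagged = tail < alpha),
    class = c("outlier_report", "data.frame"), alpha = alpha
  )
}

#' Percentile bootstrap confidence interval for the mean
#'
#' @param values numeric vector (>= 2 values).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed; identical seeds give identical intervals.
#' @return numeric `c(lower, upper)` percentile interval of the resampled
#'   means.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = 1) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(values)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Circular mean direction
#'
#' Direction of the mean resultant vector, `atan2(mean sin, mean cos)`.
#'
#' @param angles radians.
#' @return mean direction in (-pi, pi]; `NA` with a warning when the
#'   resultant length is numerically zero (undefined mean).
#' @export
circular_mean <- function(angles) {
  s <- mean(sin(angles))
  c_ <- mean(cos(angles))
  r <- sqrt(s^2 + c_^2)
  if (r < 1e-12) {
    warning("resultant length ~ 0: circular mean undefined", call. = FALSE)
    return(NA_real_)
  }
  atan2(s, c_)
}

mean_resultant <- function(angles) {
  sqrt(mean(sin(angles))^2 + mean(cos(angles))^2)
}

# half-angle of the (1 - alpha) confidence cone for the circular mean
# (Zar 1999, eq. 26.24/26.25; the formula behind CircStat's circ_confmean)
circ_conf_halfangle <- function(angles, alpha = 0.05) {
  n <- length(angles)
  r <- mean_resultant(angles)
  R <- n * r
  c2 <- qchisq(1 - alpha, df = 1)
  arg <- if (r < 0.9) {
    sqrt((2 * n * (2 * R^2 - n * c2)) / (4 * n - c2)) / R
  } else {
    sqrt(n^2 - (n^2 - R^2) * exp(c2 / n)) / R
  }
  if (!is.finite(arg) || arg > 1) return(NA_real_) # too dispersed for a cone
  acos(arg)
}

#' One-sample test of the mean phase delay
#'
#' Confidence-cone test that the circular mean of within-subject phase
#' differences deviates from zero: the null direction 0 is rejected when it
#' falls outside the `1 - alpha` confidence interval of the circular mean.
#' The mean delay is also reported in milliseconds at the stated frequency.
#'
#' @param deltas per-subject phase differences in radians.
#' @param f_context frequency (Hz) used to convert the mean direction to a
#'   delay in ms (positive = the minuend condition is later, under the
#'   [lsq_phase()] convention).
#' @param alpha test level (default 0.05).
#' @return list with `mean_phase`, `mean_delay_ms`, `ci_halfangle`,
#'   `reject`, and `p_proxy` (smallest level at which 0 is excluded, found
#'   by bisection; a proxy, not an exact p-value).
#' @export
paired_phase_test <- function(deltas, f_context, alpha = 0.05) {
  mu <- circular_mean(deltas)
  if (is.na(mu)) {
    return(list(mean_phase = NA_real_, mean_delay_ms = NA_real_,
                ci_halfangle = NA_real_, reject = NA, p_proxy = NA_real_))
  }
  h <- circ_conf_halfangle(deltas, alpha)
  dev <- abs(wrap_pi(0 - mu))
  reject <- !is.na(h) && dev > h
  # smallest alpha with rejection, by bisection on the cone half-angle
  p <- (function() {
    h50 <- circ_conf_halfangle(deltas, 0.5)
    if (is.na(h50) || dev <= h50) return(1)
    lo <- 1e-8; hi <- 0.5
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      hm <- circ_conf_halfangle(deltas, mid)
      if (is.na(hm) || dev <= hm) lo <- mid else hi <- mid
    }
    hi
  })()
  list(mean_phase = mu,
       mean_delay_ms = phase_to_delay(mu, 0, f_context),
       ci_halfangle = h, reject = reject, p_proxy = p)
}

# Fisher's approximation to the von Mises ML concentration
kappa_from_r <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams two-sample test for equal mean directions
#'
#' Concentration-corrected F test comparing the mean directions of two
#' circular samples.  A `valid` flag is reported: the test assumes von
#' Mises samples with a common, adequately large concentration (pooled
#' resultant length >= 0.45 and >= 5 observations per sample).
#'
#' @param angles_a,angles_b the two samples, radians.
#' @return list with `F`, `p`, `df1`, `df2`, `kappa`, `valid` (with a
#'   warning when the validity check fails).
#' @export
watson_williams <- function(angles_a, angles_b) {
  n1 <- length(angles_a); n2 <- length(angles_b); n <- n1 + n2
  if (n1 < 5L || n2 < 5L) warning("Watson-Williams: fewer than 5 per sample",
                                  call. = FALSE)
  r1 <- n1 * mean_resultant(angles_a)
  r2 <- n2 * mean_resultant(angles_b)
  rall <- n * mean_resultant(c(angles_a, angles_b))
  rw <- (r1 + r2) / n
  valid <- rw >= 0.45 && n1 >= 5L && n2 >= 5L
  if (!valid) warning("Watson-Williams validity check failed (dispersed or small samples)",
                      call. = FALSE)
  kp <- kappa_from_r(rw)
  corr <- 1 + 3 / (8 * kp)
  Fstat <- corr * ((n - 2) * (r1 + r2 - rall)) / (n - (r1 + r2))
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = pf(Fstat, 1, n - 2, lower.tail = FALSE),
       df1 = 1, df2 = n - 2, kappa = kp, valid = valid)
}

#' Correlation between binocular ADI excess and BSI asymmetry
#'
#' Pearson correlation (with two-sided p) between the per-subject
#' difference in ADI (binocular - monocular) and the per-subject difference
#' in BSI (AE - FE), computed after outlier exclusion.
#'
#' @param adi_diff per-subject `ADI_bino - ADI_mono`.
#' @param bsi_diff per-subject `BSI_AE - BSI_FE`.
#' @return list with `r`, `p`, `n`.
#' @export
adi_bsi_correlation <- function(adi_diff, bsi_diff) {
  if (length(adi_diff) != length(bsi_diff)) stop("unpaired inputs", call. = FALSE)
  ok <- is.finite(adi_diff) & is.finite(bsi_diff)
  if (sum(ok) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (var(adi_diff[ok]) == 0 || var(bsi_diff[ok]) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(adi_diff[ok], bsi_diff[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
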