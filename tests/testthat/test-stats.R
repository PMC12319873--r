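test_that("Mahalanobis outlier rule flags by the chi-squared tail", {
  set.seed(1)
  pts <- matrix(rnorm(60), ncol = 2)
  rep1 <- mahalanobis_outliers(pts)
  expect_false(rep1$flagged[which.min(rep1$mahalanobis_sq)])
  # known standard 2-D normal parameters: (3,4) has D^2 = 25 and the
  # chi-squared(2) tail is exp(-25/2)
  rep2 <- mahalanobis_outliers(rbind(c(0, 0), c(3, 4)), alpha = 0.01,
                               center = c(0, 0), cov = diag(2))
  expect_equal(rep2$mahalanobis_sq[2], 25)
  expect_equal(rep2$tail_prob[2], exp(-12.5), tolerance = 1e-9)
  expect_true(rep2$flagged[2])
  expect_false(rep2$flagged[1])
  expect_error(mahalanobis_outliers(pts, alpha = 0.6), "alpha")
  expect_error(
    mahalanobis_outliers(cbind(1:10, 1:10)), "singular|condition")
})

test_that("outlier flags are invariant to affine transforms", {
  set.seed(2)
  pts <- matrix(rnorm(80), ncol = 2)
  base <- mahalanobis_outliers(pts)
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2, 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    shifted <- pts %*% t(A) + matrix(rnorm(2), nrow(pts), 2, byrow = TRUE)
    tr <- mahalanobis_outliers(shifted)
    expect_equal(tr$mahalanobis_sq, base$mahalanobis_sq, tolerance = 1e-9)
    expect_identical(tr$flagged, base$flagged)
  }
})

test_that("bootstrap CI: degenerate, deterministic, calibrated, shrinking", {
  expect_equal(bootstrap_ci(rep(3.2, 10)), c(3.2, 3.2))
  xv <- rnorm(20)
  expect_identical(bootstrap_ci(xv, seed = 5), bootstrap_ci(xv, seed = 5))
  expect_error(bootstrap_ci(1), "at least 2")
  # coverage of the true mean near the nominal level
  set.seed(33)
  cover <- replicate(300, {
    x <- rnorm(50, mean = 1)
    ci <- bootstrap_ci(x, n_boot = 400, seed = sample.int(1e6, 1))
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
  # width shrinks roughly like 1/sqrt(n)
  set.seed(7)
  w50 <- diff(bootstrap_ci(rnorm(50), n_boot = 2000, seed = 1))
  w800 <- diff(bootstrap_ci(rnorm(800), n_boot = 2000, seed = 1))
  expect_lt(w800, w50 / 2)
})

test_that("circular mean handles wrapping and matches a grid oracle", {
  expect_equal(circular_mean(c(0, pi / 2)), pi / 4)
  wrapped <- circular_mean(c(-pi + 0.01, pi - 0.01))
  expect_lt(abs(abs(wrapped) - pi), 1e-9)
  set.seed(4)
  for (i in 1:5) {
    th <- rvm(25, mu = runif(1, -pi, pi), kappa = 2)
    grid <- seq(-pi, pi, by = 1e-4)
    oracle <- grid[which.max(vapply(grid, function(m) sum(cos(th - m)),
                                    numeric(1)))]
    expect_lt(abs(wrap_pi(circular_mean(th) - oracle)), 2e-4)
  }
  expect_warning(out <- circular_mean(c(0, pi)), "undefined")
  expect_true(is.na(out))
})

test_that("one-sample phase test: null, concentrated, and type-I error", {
  null_res <- paired_phase_test(rep(0, 20), f_context = 8)
  expect_false(null_res$reject)
  expect_equal(null_res$mean_delay_ms, 0)
  set.seed(10)
  conc <- wrap_pi(pi / 4 + rvm(30, 0, kappa = 60))
  res <- paired_phase_test(conc, f_context = 8)
  expect_true(res$reject)
  expect_equal(res$mean_delay_ms, 15.625, tolerance = 0.8)
  expect_lt(res$p_proxy, 0.01)
  # nominal type-I error on mean-zero von Mises samples
  set.seed(20)
  rejections <- replicate(500, {
    paired_phase_test(rvm(20, 0, kappa = 2), f_context = 8)$reject
  })
  rate <- mean(rejections)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("Watson-Williams: identity, power, and formula oracle", {
  set.seed(6)
  a <- rvm(20, 0, kappa = 5)
  ww_same <- watson_williams(a, a)
  expect_lt(ww_same$F, 1e-9)
  expect_gt(ww_same$p, 0.99)
  # power against a 0.6 rad separation at kappa = 5
  hits <- replicate(200, {
    x <- rvm(20, 0, kappa = 5); y <- rvm(20, 0.6, kappa = 5)
    watson_williams(x, y)$p < 0.05
  })
  expect_gt(mean(hits), 0.9)
  # independent transliteration of the corrected F statistic
  ww_oracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    R1 <- sqrt(sum(cos(x))^2 + sum(sin(x))^2)
    R2 <- sqrt(sum(cos(y))^2 + sum(sin(y))^2)
    R <- sqrt(sum(cos(c(x, y)))^2 + sum(sin(c(x, y)))^2)
    rw <- (R1 + R2) / n
    k <- if (rw < 0.53) 2 * rw + rw^3 + 5 * rw^5 / 6 else
      if (rw < 0.85) -0.4 + 1.39 * rw + 0.43 / (1 - rw) else
        1 / (rw^3 - 4 * rw^2 + 3 * rw)
    (1 + 3 / (8 * k)) * ((n - 2) * (R1 + R2 - R)) / (n - (R1 + R2))
  }
  x <- rvm(15, 0.2, kappa = 4); y <- rvm(18, 0.7, kappa = 4)
  expect_equal(watson_williams(x, y)$F, ww_oracle(x, y), tolerance = 1e-6)
  small_w <- capture_warnings(watson_williams(rvm(3, 0, 2), rvm(3, 0, 2)))
  expect_true(any(grepl("fewer than 5", small_w)))
  # type-I error near nominal under a common mean direction
  set.seed(21)
  t1 <- replicate(400, {
    watson_williams(rvm(15, 1, kappa = 4), rvm(15, 1, kappa = 4))$p < 0.05
  })
  expect_gt(mean(t1), 0.02)
  expect_lt(mean(t1), 0.09)
})

test_that("circular operations are rotation invariant", {
  set.seed(9)
  th <- rvm(25, 0.5, kappa = 3)
  for (rot in c(0.7, -2.1)) {
    expect_equal(wrap_pi(circular_mean(th + rot) - rot), circular_mean(th),
                 tolerance = 1e-9)
    ww0 <- watson_williams(th, th + 0.5)
    wwr <- watson_williams(wrap_pi(th + rot), wrap_pi(th + 0.5 + rot))
    expect_equal(wwr$F, ww0$F, tolerance = 1e-9)
  }
})

test_that("ADI-BSI correlation: exact lines, guards, planted recovery", {
  x <- seq(0.1, 1, length.out = 10)
  expect_equal(adi_bsi_correlation(x, x)$r, 1)
  expect_equal(adi_bsi_correlation(x, -x + 2)$r, -1)
  expect_error(adi_bsi_correlation(x, rep(1, 10)), "zero variance")
  expect_error(adi_bsi_correlation(x[1:2], x[1:2]), "at least 3")
  # synthetic population: binocular ADI excess generated from the BSI
  # asymmetry plus noise, correlation near the generating value
  set.seed(13)
  reps <- replicate(60, {
    bsi_diff <- rnorm(36, 0.35, 0.15)
    adi_diff <- 0.5 * bsi_diff + rnorm(36, 0, 0.04)
    adi_bsi_correlation(adi_diff, bsi_diff)$r
  })
  r_gen <- 0.5 * 0.15 / sqrt((0.5 * 0.15)^2 + 0.04^2)
  expect_lt(abs(mean(reps) - r_gen), 0.05)
  expect_gt(r_gen, 0.85) # the regime mirrors a strong observed coupling
})
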