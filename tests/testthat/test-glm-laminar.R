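test_that("noiseless simulation is recovered exactly by the GLM", {
  b <- quick_bold(noise_sd = 0)
  g <- fit_block_glm(b)
  expect_lt(max(abs(g$beta[, colnames(b$betas_true)] - b$betas_true)), 1e-6)
  expect_lt(max(g$residual_sd), 1e-6)
})

test_that("an all-zero time series yields zero betas and residual sd", {
  ev <- make_block_design(1, 18, 12, seed = 1)
  z <- matrix(0, nrow = 3, ncol = 51)
  g <- fit_block_glm(z, events = ev, tr = 2)
  expect_equal(unname(g$beta), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(unname(g$residual_sd), rep(0, 3))
})

test_that("simulation is seed-deterministic and seeds differ", {
  b1 <- quick_bold(noise_sd = 0.5, seed = 9)
  b2 <- quick_bold(noise_sd = 0.5, seed = 9)
  b3 <- quick_bold(noise_sd = 0.5, seed = 10)
  expect_identical(b1$data, b2$data)
  expect_false(identical(b1$data, b3$data))
})

test_that("beta estimates are unbiased under AR(1) noise", {
  mesh <- make_cortical_ribbon("slab", 64, thickness = 2)
  truth <- laminar_truth(adi = 0.3)
  ev <- make_block_design(3, 18, 12, seed = 5)
  n_rep <- 100
  errs <- replicate(n_rep, NA_real_)
  for (r in seq_len(n_rep)) {
    b <- simulate_bold_run(mesh, truth, ev, noise_sd = 0.5, seed = 100 + r,
                           spacing = 0.7)
    g <- fit_block_glm(b)
    errs[r] <- mean(g$beta[, "FE"] - b$betas_true[, "FE"])
  }
  mc_ci <- 3.5 * sd(errs) / sqrt(n_rep)
  expect_lt(abs(mean(errs)), mc_ci + 1e-3)
})

test_that("rank-deficient designs are rejected naming the aliased column", {
  b <- quick_bold()
  bad_motion <- matrix(1, nrow = ncol(b$data), ncol = 1,
                       dimnames = list(NULL, "motion_flat"))
  expect_error(fit_block_glm(b, motion = bad_motion), "motion_flat")
})

test_that("vein rule flags by intensity and by response, whole columns", {
  mesh <- small_wedge()
  nv <- nrow(mesh$vertices_white)
  vein <- c(5L, 60L, 120L)
  truth <- laminar_truth(vein_vertices = vein)
  b <- quick_bold(mesh = mesh, truth = truth)
  g <- fit_block_glm(b)
  vm <- vein_mask(g)
  present <- vein[vein %in% unique(g$vertex_id)]
  expect_true(all(vm$vertex_flag[present]))
  expect_lt(mean(vm$vertex_flag, na.rm = TRUE), 0.2)
  # column completeness: every voxel of a flagged vertex is excluded
  for (v in which(vm$vertex_flag)) {
    expect_true(all(vm$voxel_excluded[g$vertex_id == v]))
  }
  expect_true(all(!vm$voxel_excluded[!vm$vertex_flag[g$vertex_id]]))
})

test_that("vein thresholds act at the stated cutoffs", {
  # two synthetic columns: one at 0.6x average intensity, one at 12 PSC
  g <- structure(list(
    beta = cbind(AE = c(1, 1, 12, 1), FE = c(1, 1, 12, 1),
                 binocular = c(1, 1, 12, 1)),
    mean_epi = c(100, 55, 100, 100), # vertex 2 at ~0.62x of the average
    conditions = c("AE", "FE", "binocular"),
    vertex_id = 1:4, n_vertices = 4), class = "glm_result")
  vm <- vein_mask(g)
  expect_equal(which(vm$vertex_flag), c(2L, 3L))
})

test_that("vein exclusion restores the planted laminar profile", {
  mesh <- small_wedge()
  vein <- seq(10L, 390L, by = 40L)
  truth <- laminar_truth(adi = 0.3, vein_vertices = vein)
  b <- quick_bold(mesh = mesh, truth = truth)
  g <- fit_block_glm(b)
  vm <- vein_mask(g)
  with_veins <- laminar_profile(g, depth = NULL)
  cleaned <- laminar_profile(g, depth = NULL, mask = vm)
  truth_clean <- laminar_profile(
    structure(modifyList(unclass(g), list(beta = b$betas_true)),
              class = "glm_result"),
    depth = NULL, mask = vm)
  fe_c <- cleaned$mean_beta[cleaned$condition == "FE"]
  fe_t <- truth_clean$mean_beta[truth_clean$condition == "FE"]
  fe_v <- with_veins$mean_beta[with_veins$condition == "FE"]
  expect_lt(max(abs(fe_c - fe_t)), 1e-6)      # exact after exclusion
  expect_gt(max(abs(fe_v - fe_t)), 0.05)      # contaminated before
})

test_that("uniform betas give a flat profile and empty bins are NA", {
  b <- quick_bold()
  g <- fit_block_glm(b)
  g$beta[] <- 1
  prof <- laminar_profile(g, depth = NULL, n_bins = 3)
  expect_equal(prof$mean_beta, rep(1, nrow(prof)))
  # depths confined to [0, 0.5): upper bins must be flagged missing
  g2 <- g
  g2$depth_true <- g$depth_true * 0.49
  prof2 <- laminar_profile(g2, depth = NULL, n_bins = 3)
  expect_true(all(is.na(prof2$mean_beta[prof2$bin == 3])))
  expect_equal(prof2$n_voxels[prof2$bin == 3], rep(0L, 3))
})

test_that("ADI arithmetic, flags, and scale invariance", {
  expect_equal(compute_adi(0.5, 1.0), 0.5)
  expect_equal(compute_adi(1, 1), 0)
  expect_true(is.na(compute_adi(0.5, 0)))
  ae <- runif(5, 0.2, 1); fe <- runif(5, 0.5, 2)
  for (k in c(0.1, 3, 42)) {
    expect_equal(compute_adi(k * ae, k * fe), compute_adi(ae, fe))
  }
})

test_that("planted flat ADI is recovered flat across layers", {
  b <- quick_bold(truth = laminar_truth(adi = 0.3))
  g <- fit_block_glm(b)
  adi <- adi_profile(laminar_profile(g, depth = NULL))
  expect_lt(max(abs(adi$adi - 0.3)), 1e-6)
})

test_that("ocular ROI selection sizes, symmetry, and accuracy", {
  set.seed(2)
  x <- rnorm(1000)
  rois <- select_ocular_rois(x, rep(0, 1000), frac = 0.10)
  expect_length(rois$AE_biased, 100)
  expect_length(rois$FE_biased, 100)
  # antisymmetric map: swapping the eyes swaps the sets
  r2 <- select_ocular_rois(rep(0, 1000), x, frac = 0.10)
  expect_identical(rois$AE_biased, r2$FE_biased)
  expect_identical(rois$FE_biased, r2$AE_biased)
  expect_error(select_ocular_rois(x[1:5], rep(0, 5), frac = 0.05), "no vertices")
  # planted ocular-dominance map at high SNR: selected vertices carry the
  # matching true preference
  b <- quick_bold(noise_sd = 0.2, partial_volume = 0.2, seed = 4)
  g <- fit_block_glm(b)
  nv <- g$n_vertices
  ae_s <- map_voxels_to_surface(g$beta[, "AE"], g$vertex_id, nv)
  fe_s <- map_voxels_to_surface(g$beta[, "FE"], g$vertex_id, nv)
  sel <- select_ocular_rois(ae_s, fe_s, frac = 0.10)
  pref_true <- map_voxels_to_surface(b$weights_true[, "AE"] - b$weights_true[, "FE"],
                                     g$vertex_id, nv)
  expect_gt(mean(pref_true[sel$AE_biased] > 0), 0.95)
  expect_gt(mean(pref_true[sel$FE_biased] < 0), 0.95)
})

test_that("split-half ROI extraction is symmetric and unbiased", {
  b <- quick_bold()
  g <- fit_block_glm(b)
  sh <- split_half_rois(list(g, g), depth = NULL)
  single <- laminar_profile(g, depth = NULL,
                            roi = select_ocular_rois(
                              map_voxels_to_surface(g$beta[, "AE"], g$vertex_id, g$n_vertices),
                              map_voxels_to_surface(g$beta[, "FE"], g$vertex_id, g$n_vertices))$AE_biased)
  expect_equal(sh$AE_biased$mean_beta, single$mean_beta, tolerance = 1e-9)
  expect_error(split_half_rois(list(g)), ">= 2 runs")
  # swapped halves give the same average
  b2 <- quick_bold(noise_sd = 0.3, seed = 21)
  g2 <- fit_block_glm(b2)
  sh12 <- split_half_rois(list(g, g2), depth = NULL)
  sh21 <- split_half_rois(list(g2, g), depth = NULL)
  expect_equal(sh12$AE_biased$mean_beta, sh21$AE_biased$mean_beta,
               tolerance = 1e-9)
})
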