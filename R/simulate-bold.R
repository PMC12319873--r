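# Ground-truthed BOLD simulation on a cortical ribbon.
#
# Voxel responses follow the linear ocular-channel model the analyses assume:
# each voxel mixes an amblyopic-eye (AE) and fellow-eye (FE) channel with
# non-negative weights drawn from an ocular-dominance-column-like band
# pattern, scaled by a depth-dependent gain with a superficial venous bias.
# In the binocular condition each channel is attenuated by its planted
# binocular suppression index (BSI).  Vein-contaminated columns get amplified
# signal and reduced mean intensity so the intensity/response vein rule can
# find them.

#' Planted laminar ground truth
#'
#' Holds depth profiles of the two monocular channel responses, the implied
#' amblyopic deficit index `adi = (FE - AE)/FE`, the planted per-eye
#' binocular suppression indices, and the set of vein-contaminated vertices.
#' Scalar arguments are expanded to constant depth profiles.
#'
#' @param depths depth grid in \[0, 1\] on which profiles are defined.
#' @param profile_FE fellow-eye channel response (percent signal change) per
#'   depth; scalar or vector on `depths`.
#' @param adi amblyopic deficit index per depth (dimensionless); the AE
#'   profile is derived as `profile_FE * (1 - adi)`.
#' @param bsi_AE,bsi_FE planted binocular suppression per eye per depth,
#'   values in (-1, 1\].
#' @param vein_vertices integer indices of vein-contaminated vertices
#'   (columns), may be empty.
#' @return object of class `laminar_truth`.
#' @export
laminar_truth <- function(depths = seq(0, 1, length.out = 21),
                          profile_FE = 2, adi = 0.3,
                          bsi_AE = 0.4, bsi_FE = 0.05,
                          vein_vertices = integer()) {
  n <- length(depths)
  fe <- rep_len(profile_FE, n)
  adi <- rep_len(adi, n)
  ae <- fe * (1 - adi)
  bsi_AE <- rep_len(bsi_AE, n)
  bsi_FE <- rep_len(bsi_FE, n)
  if (any(fe < 0) || any(ae < 0)) stop("profiles must be non-negative", call. = FALSE)
  if (any(bsi_AE <= -1 | bsi_AE > 1) || any(bsi_FE <= -1 | bsi_FE > 1)) {
    stop("BSI values must lie in (-1, 1]", call. = FALSE)
  }
  structure(
    list(depths = depths, profile_AE = ae, profile_FE = fe, adi_true = adi,
         bsi_true_AE = bsi_AE, bsi_true_FE = bsi_FE,
         vein_vertices = as.integer(vein_vertices)),
    class = "laminar_truth"
  )
}

truth_at <- function(truth, field, depth) {
  approx(truth$depths, truth[[field]], xout = depth, rule = 2)$y
}

# Ocular preference weights: smooth sinusoidal bands along y mimicking ODCs.
# partial_volume in [0, 1] mixes the band pattern toward 0.5/0.5; weights sum
# to 1 per voxel, and integer band counts keep the two channel means equal.
odc_weights <- function(y, extent_y, odc_period, partial_volume) {
  n_bands <- max(1, round(extent_y / odc_period))
  pref <- (1 + sin(2 * pi * n_bands * y / extent_y)) / 2
  w_ae <- (1 - partial_volume) * pref + partial_volume * 0.5
  cbind(AE = w_ae, FE = 1 - w_ae)
}

#' Simulate a block-design BOLD run on a ribbon
#'
#' Generates voxel time series on a regular grid inside the ribbon:
#' `signal = baseline * (1 + sum_c beta_c/100 * regressor_c(t)) + AR(1) noise`,
#' where the condition betas follow the planted laminar truth, the ocular
#' mixing weights, and a depth gain `1 + gain_slope * (1 - depth)` emulating
#' the superficial venous amplitude bias.  Voxel depths use the closed-form
#' equivolume relation [alpha_from_frac()] on the voxel's own column — the
#' analytic truth, independent of the surface-interpolation estimator.
#'
#' @param mesh a `mesh_pair`.
#' @param truth a `laminar_truth`.
#' @param events event table from [make_block_design()].
#' @param tr repetition time (s); must divide the run length.
#' @param noise_sd AR(1) noise standard deviation in percent-signal-change
#'   units (0 for noiseless).
#' @param seed integer seed.
#' @param spacing voxel grid spacing in mm.
#' @param partial_volume strength of partial-volume mixing between the two
#'   ocular channels (0 = pure columns, 1 = fully mixed).
#' @param odc_period ocular-dominance band period in mm.
#' @param gain_slope slope of the superficial depth gain.
#' @param ar_rho AR(1) autocorrelation of the noise.
#' @param vein_gain signal amplification factor in vein columns.
#' @param vein_intensity mean-intensity factor in vein columns (< 0.7 so the
#'   intensity rule triggers).
#' @param baseline mean signal intensity (arbitrary units).
#' @return object of class `bold_run`: `data` (voxels x volumes), `coords`,
#'   `vertex_id`, `depth_true`, `weights_true`, `betas_true` (voxels x 3
#'   conditions, PSC), `baseline`, `events`, `tr`, and the generating
#'   parameters in attributes.
#' @export
simulate_bold_run <- function(mesh, truth, events, tr = 2, noise_sd = 0,
                              seed = 1, spacing = 0.5, partial_volume = 0.3,
                              odc_period = 2, gain_slope = 1, ar_rho = 0.3,
                              vein_gain = 3, vein_intensity = 0.6,
                              baseline = 100) {
  run_s <- design_duration(events)
  if (abs(run_s / tr - round(run_s / tr)) > 1e-9) {
    stop("TR must divide the run length", call. = FALSE)
  }
  n_vols <- as.integer(round(run_s / tr))
  geom <- attr(mesh, "geometry")

  g <- ribbon_grid(mesh, spacing)
  asg <- assign_columns(mesh, g$coords)
  e <- mesh$vertices_white[mesh$faces[, 1], ] - mesh$vertices_white[mesh$faces[, 2], ]
  max_dist <- stats::median(sqrt(rowSums(e^2)))
  gm <- asg$t_raw >= 0 & asg$t_raw <= 1 & asg$perp <= max_dist
  coords <- g$coords[gm, , drop = FALSE]
  vid <- asg$vertex_id[gm]
  tt <- asg$t_raw[gm]
  depth <- alpha_from_frac(tt, mesh$area_pial[vid], mesh$area_white[vid])
  n_vox <- nrow(coords)

  w <- odc_weights(coords[, "y"], geom$extent[2], odc_period, partial_volume)
  gain <- 1 + gain_slope * (1 - depth)
  is_vein <- vid %in% truth$vein_vertices
  gain[is_vein] <- gain[is_vein] * vein_gain
  base_v <- rep(baseline, n_vox)
  base_v[is_vein] <- baseline * vein_intensity

  p_ae <- truth_at(truth, "profile_AE", depth)
  p_fe <- truth_at(truth, "profile_FE", depth)
  s_ae <- 1 - truth_at(truth, "bsi_true_AE", depth)
  s_fe <- 1 - truth_at(truth, "bsi_true_FE", depth)
  betas <- cbind(
    AE = gain * w[, "AE"] * p_ae,
    FE = gain * w[, "FE"] * p_fe,
    binocular = gain * (w[, "AE"] * s_ae * p_ae + w[, "FE"] * s_fe * p_fe)
  )

  X <- vapply(FMRI_CONDITIONS, function(cnd) block_regressor(events, cnd, tr, n_vols),
              numeric(n_vols)) # n_vols x 3
  data <- base_v * (1 + (betas %*% t(X)) / 100)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    innov_sd <- noise_sd * sqrt(1 - ar_rho^2)
    noise <- matrix(rnorm(n_vox * n_vols, sd = innov_sd), n_vox, n_vols)
    for (j in 2:n_vols) noise[, j] <- noise[, j] + ar_rho * noise[, j - 1]
    data <- data + base_v * noise / 100
  }

  structure(
    list(data = data, coords = coords, vertex_id = vid, depth_true = depth,
         t = tt, weights_true = w, betas_true = betas, baseline = base_v,
         is_vein_voxel = is_vein, events = events, tr = tr,
         n_vertices = nrow(mesh$vertices_white),
         grid = list(dims = g$dims, spacing = g$spacing, origin = g$origin,
                     index = which(gm))),
    class = "bold_run",
    params = list(noise_sd = noise_sd, seed = seed, spacing = spacing,
                  partial_volume = partial_volume, odc_period = odc_period,
                  gain_slope = gain_slope, ar_rho = ar_rho,
                  vein_gain = vein_gain, vein_intensity = vein_intensity)
  )
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run: %d voxels x %d volumes, TR %.1f s>\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}
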