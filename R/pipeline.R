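# End-to-end orchestration of the two pipeline arms.

#' Default pipeline configuration
#'
#' All analysis thresholds default to their canonical values: vein rule
#' 0.70 x average intensity / 10 PSC, ocular-bias ROI fraction 0.10 per
#' side, amplitude band 1-30 Hz over the last 5 s of each trial, phase band
#' 6-9 Hz over 1.25-5 s (integer cycle counts of both tags), multivariate
#' outlier level 0.01.  Simulation parameters set the planted effects and
#' problem sizes; see the package vignette for the rationale behind each.
#'
#' @param seed master integer seed.
#' @param ... named overrides of any `fmri` or `eeg` sub-list entry, e.g.
#'   `fmri = list(noise_sd = 0)`.
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    fmri = list(
      n_runs = 4, n_per_condition = 3, block_s = 18, fix_s = 12, tr = 2,
      shape = "wedge", n_vertices = 400, thickness = 2, ratio = 2,
      spacing = 0.4, n_surfaces = 11,
      profile_FE = 2, adi = 0.3, bsi_AE = 0.4, bsi_FE = 0.05,
      vein_frac = 0.05, noise_sd = 0.2, partial_volume = 0.3,
      drift_order = 3, vein_intensity_frac = 0.7, vein_psc_max = 10,
      roi_frac = 0.1, n_bins = 3
    ),
    eeg = list(
      n_subjects = 10, n_trials = 20, srate = 1000, trial_s = 6, gap_s = 2,
      amp_band = c(1, 30), phase_band = c(6, 9),
      amp_window = c(1, 6), phase_window = c(1.25, 5),
      alpha_outlier = 0.01, n_boot = 2000, ci_level = 0.95,
      adi_mean = 0.3, adi_sd = 0.1,
      bsi_AE_mean = 0.4, bsi_AE_sd = 0.15,
      bsi_FE_mean = 0.05, bsi_FE_sd = 0.05,
      amp1_FE = 2, amp2_FE = 1, im_amp = 0.5,
      delay_AE_ms = 12.81, noise_sd = 3
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

provenance <- function(config, seed) {
  list(config_hash = rlang::hash(unclass(config)), seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Run the laminar fMRI arm end to end
#'
#' Simulate -> equivolume depth -> per-run GLM -> vein mask -> laminar
#' profiles -> ADI (monocular, and binocular via ocular-biased ROIs) ->
#' inverted encoding model -> per-depth BSI.  Every numeric table carries
#' the configuration hash and seed, so a rerun with the same configuration
#' reproduces it exactly.
#'
#' @param config a `pipeline_config` (or its `fmri` part embedded in one).
#' @param out_dir optional directory to persist depth NIfTI, profile /
#'   index TSVs, and a JSON run manifest.
#' @return list with `depth`, `layers`, `profiles`, `adi_mono`, `adi_bino`,
#'   `iem` (BSI profile), `vein`, `rois`, `truth`, `recovery` (errors vs
#'   the planted truth), and `provenance`.
#' @export
run_fmri_arm <- function(config = pipeline_config(), out_dir = NULL) {
  fc <- config$fmri
  seed <- config$seed

  mesh <- make_cortical_ribbon(fc$shape, n_vertices = fc$n_vertices,
                               thickness = fc$thickness, ratio = fc$ratio)
  nv <- nrow(mesh$vertices_white)
  set.seed(seed)
  vein <- sort(sample.int(nv, max(0L, round(fc$vein_frac * nv))))
  truth <- laminar_truth(profile_FE = fc$profile_FE, adi = fc$adi,
                         bsi_AE = fc$bsi_AE, bsi_FE = fc$bsi_FE,
                         vein_vertices = vein)

  runs <- lapply(seq_len(fc$n_runs), function(r) {
    ev <- make_block_design(fc$n_per_condition, fc$block_s, fc$fix_s,
                            seed = seed + 17L * r)
    simulate_bold_run(mesh, truth, ev, tr = fc$tr, noise_sd = fc$noise_sd,
                      seed = seed + 1000L + r, spacing = fc$spacing,
                      partial_volume = fc$partial_volume)
  })

  depth <- equivolume_depth(mesh, spacing = fc$spacing,
                            n_surfaces = fc$n_surfaces)
  glms <- lapply(runs, fit_block_glm, drift_order = fc$drift_order)
  glm_avg <- average_glm(glms)
  vmask <- vein_mask(glm_avg, intensity_frac = fc$vein_intensity_frac,
                     psc_max = fc$vein_psc_max)

  profiles <- laminar_profile(glm_avg, depth = depth, mask = vmask,
                              n_bins = fc$n_bins)
  adi_mono <- adi_profile(profiles)
  layers <- assign_layers(depth)

  ae_s <- map_voxels_to_surface(glm_avg$beta[, "AE"], glm_avg$vertex_id, nv)
  fe_s <- map_voxels_to_surface(glm_avg$beta[, "FE"], glm_avg$vertex_id, nv)
  rois <- select_ocular_rois(ae_s, fe_s, frac = fc$roi_frac)
  prof_ae_roi <- laminar_profile(glm_avg, depth = depth, mask = vmask,
                                 roi = rois$AE_biased, n_bins = fc$n_bins)
  prof_fe_roi <- laminar_profile(glm_avg, depth = depth, mask = vmask,
                                 roi = rois$FE_biased, n_bins = fc$n_bins)
  bino_ae <- prof_ae_roi$mean_beta[prof_ae_roi$condition == "binocular"]
  bino_fe <- prof_fe_roi$mean_beta[prof_fe_roi$condition == "binocular"]
  adi_bino <- data.frame(bin = seq_len(fc$n_bins),
                         adi = compute_adi(bino_ae, bino_fe))

  iem <- iem_bsi_profile(glm_avg, depth = depth, mask = vmask,
                         n_bins = fc$n_bins)

  bin_mid <- (seq_len(fc$n_bins) - 0.5) / fc$n_bins
  recovery <- list(
    adi_mono_err = max(abs(adi_mono$adi - truth_at(truth, "adi_true", bin_mid))),
    bsi_AE_err = max(abs(iem$bsi_AE - truth_at(truth, "bsi_true_AE", bin_mid))),
    bsi_FE_err = max(abs(iem$bsi_FE - truth_at(truth, "bsi_true_FE", bin_mid))),
    vein_detect = mean(vmask$vertex_flag[truth$vein_vertices]),
    layer_volume_fractions = layer_volume_fractions(layers)
  )

  out <- list(depth = depth, layers = layers, profiles = profiles,
              adi_mono = adi_mono, adi_bino = adi_bino, iem = iem,
              vein = vmask, rois = rois, glm = glm_avg, truth = truth,
              recovery = recovery, provenance = provenance(config, seed))
  if (!is.null(out_dir)) persist_fmri(out, out_dir)
  out
}

persist_fmri <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_depth_nifti(res$depth, file.path(out_dir, "depth.nii.gz"))
  stamp <- function(df) {
    df$config_hash <- res$provenance$config_hash
    df$seed <- res$provenance$seed
    df
  }
  write_tsv(stamp(res$profiles), file.path(out_dir, "profiles.tsv"))
  write_tsv(stamp(res$adi_mono), file.path(out_dir, "adi_mono.tsv"))
  write_tsv(stamp(res$adi_bino), file.path(out_dir, "adi_bino.tsv"))
  write_tsv(stamp(res$iem), file.path(out_dir, "bsi_iem.tsv"))
  jsonlite::write_json(res$provenance, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

subject_truth <- function(ec, seed) {
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ssvep_truth(
    amp1_FE = ec$amp1_FE, amp2_FE = ec$amp2_FE,
    adi = clamp(rnorm(1, ec$adi_mean, ec$adi_sd), 0, 0.9),
    im_amp = ec$im_amp,
    bsi_AE = clamp(rnorm(1, ec$bsi_AE_mean, ec$bsi_AE_sd), -0.5, 0.95),
    bsi_FE = clamp(rnorm(1, ec$bsi_FE_mean, ec$bsi_FE_sd), -0.5, 0.95),
    delay_AE_ms = ec$delay_AE_ms, noise_sd = ec$noise_sd
  )
}

#' SSVEP amplitude, index, and phase analysis of one recording
#'
#' The full single-subject EEG analysis: band-pass 1-30 Hz, Laplacian
#' reference, per-condition trial means over the last 5 s, amplitude
#' spectra, harmonic-summed tagged amplitudes (averaged over the two tag
#' assignments), intermodulation amplitude, ADI/BSI indices per spatial
#' frequency, and the 6-9 Hz least-squares phase analysis over 1.25-5 s.
#'
#' @param rec an `eeg_recording`.
#' @param amp_band,phase_band analysis bands (Hz).
#' @param amp_window,phase_window analysis windows (s relative to onset).
#' @return list with `amplitudes` (long table), `indices` (per spatial
#'   frequency), `im` (per spatial frequency), `phases` (long table),
#'   `delay_AE_FE_ms` (mean across tag frequencies), `phase_deltas`
#'   (radians per tag frequency).
#' @export
analyze_ssvep_recording <- function(rec, amp_band = c(1, 30),
                                    phase_band = c(6, 9),
                                    amp_window = c(1, 6),
                                    phase_window = c(1.25, 5)) {
  conds <- unique(rec$trials[, c("condition", "sf", "ocularity", "assignment",
                                 "f_AE", "f_FE")])
  lap_amp <- laplacian_reference(bandpass(rec, amp_band[1], amp_band[2]))
  lap_phs <- laplacian_reference(bandpass(rec, phase_band[1], phase_band[2]))

  amp_rows <- list()
  phs_rows <- list()
  im_rows <- list()
  for (i in seq_len(nrow(conds))) {
    cn <- conds[i, ]
    eyes <- if (cn$ocularity == "binocular") c("AE", "FE") else cn$ocularity
    avg_a <- average_trials(lap_amp, cn$condition, amp_window)
    spec <- amplitude_spectrum(avg_a)
    avg_p <- average_trials(lap_phs, cn$condition, phase_window)
    for (eye in eyes) {
      f <- if (eye == "AE") cn$f_AE else cn$f_FE
      floor_amp <- spectrum_noise_floor(
        spec, f, exclude = c(cn$f_AE, cn$f_FE, 2 * cn$f_AE, 2 * cn$f_FE,
                             cn$f_AE + cn$f_FE))
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        condition = cn$condition, sf = cn$sf, ocularity = cn$ocularity,
        assignment = cn$assignment, eye = eye, f_tag = f,
        amp_sum = tagged_amplitude(spec, f), noise_floor = floor_amp)
      ph <- lsq_phase(avg_p, f, rec$srate, t0 = phase_window[1])
      phs_rows[[length(phs_rows) + 1L]] <- data.frame(
        condition = cn$condition, sf = cn$sf, ocularity = cn$ocularity,
        assignment = cn$assignment, eye = eye, f_tag = f, phase = ph$phase,
        amplitude = ph$amplitude)
    }
    if (cn$ocularity == "binocular") {
      im_rows[[length(im_rows) + 1L]] <- data.frame(
        sf = cn$sf, assignment = cn$assignment,
        im_amp = im_amplitude(spec, cn$f_AE, cn$f_FE))
    }
  }
  amps <- do.call(rbind, amp_rows)
  phases <- do.call(rbind, phs_rows)
  im <- do.call(rbind, im_rows)
  im_by_sf <- stats::aggregate(im_amp ~ sf, im, mean)

  # tag-assignment averaging: an eye's amplitude in a viewing condition is
  # the mean of its harmonic-summed amplitude under the two assignments
  eye_amp <- function(sf, ocularity, eye) {
    mean(amps$amp_sum[amps$sf == sf & amps$ocularity == ocularity &
                        amps$eye == eye])
  }
  idx_rows <- lapply(unique(amps$sf), function(sf) {
    floor_sf <- mean(amps$noise_floor[amps$sf == sf])
    v <- indices_from_amplitudes(
      mono_AE = eye_amp(sf, "AE", "AE"), mono_FE = eye_amp(sf, "FE", "FE"),
      bino_AE = eye_amp(sf, "binocular", "AE"),
      bino_FE = eye_amp(sf, "binocular", "FE"),
      noise_floor = floor_sf)
    data.frame(sf = sf, ADI_mono = v$ADI_mono, ADI_bino = v$ADI_bino,
               BSI_AE = v$BSI_AE, BSI_FE = v$BSI_FE,
               unreliable = any(v$unreliable))
  })
  indices <- do.call(rbind, idx_rows)

  # per-tag-frequency AE-FE monocular phase difference, averaged across
  # spatial frequencies; delays converted per frequency then averaged
  fts <- sort(unique(phases$f_tag))
  deltas <- vapply(fts, function(f) {
    pa <- phases$phase[phases$ocularity == "AE" & phases$eye == "AE" &
                         phases$f_tag == f]
    pf_ <- phases$phase[phases$ocularity == "FE" & phases$eye == "FE" &
                          phases$f_tag == f]
    wrap_pi(circular_mean(pf_) - circular_mean(pa))
  }, numeric(1))
  names(deltas) <- as.character(fts)
  delay_ms <- mean(vapply(seq_along(fts),
                          function(k) wrap_pi(deltas[k]) / (2 * pi * fts[k]) * 1000,
                          numeric(1)))

  list(amplitudes = amps, indices = indices, im = im_by_sf, phases = phases,
       phase_deltas = deltas, delay_AE_FE_ms = delay_ms)
}

#' Run the EEG frequency-tagging arm end to end
#'
#' Simulates `n_subjects` dichoptic SSVEP sessions over the 12-condition
#' grid, runs the amplitude and phase pipelines per subject, and performs
#' the group analysis: multivariate outlier flagging on (ADI_mono,
#' ADI_bino), bootstrap confidence intervals, the one-sample circular test
#' of the AE-FE phase delay, and the Pearson correlation between the
#' binocular ADI excess and the BSI asymmetry.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional directory for TSV outputs and the run manifest.
#' @return list with `subjects` (per-subject index table), `im`, `outliers`,
#'   `boot_ci`, `phase_test`, `correlation`, `truth` (per-subject planted
#'   values), and `provenance`.
#' @export
run_eeg_arm <- function(config = pipeline_config(), out_dir = NULL) {
  ec <- config$eeg
  seed <- config$seed

  subj_rows <- list()
  truth_rows <- list()
  deltas_72 <- numeric(0)
  for (s in seq_len(ec$n_subjects)) {
    truth <- subject_truth(ec, seed = seed + 101L * s)
    rec <- simulate_ssvep_recording(truth, n_trials = ec$n_trials,
                                    srate = ec$srate, trial_s = ec$trial_s,
                                    gap_s = ec$gap_s, seed = seed + 7919L * s)
    res <- analyze_ssvep_recording(rec, ec$amp_band, ec$phase_band,
                                   ec$amp_window, ec$phase_window)
    idx <- res$indices
    subj_rows[[s]] <- data.frame(
      subject = s,
      ADI_mono = mean(idx$ADI_mono), ADI_bino = mean(idx$ADI_bino),
      BSI_AE = mean(idx$BSI_AE), BSI_FE = mean(idx$BSI_FE),
      im_amp = mean(res$im$im_amp),
      delay_AE_FE_ms = res$delay_AE_FE_ms,
      unreliable = any(idx$unreliable))
    truth_rows[[s]] <- data.frame(
      subject = s, adi_true = truth$adi,
      bsi_AE_true = truth$bsi[["AE"]], bsi_FE_true = truth$bsi[["FE"]],
      im_true = truth$im_amp, delay_true_ms = truth$delay_ms[["AE"]])
    deltas_72[s] <- res$phase_deltas[["7.2"]]
  }
  subjects <- do.call(rbind, subj_rows)
  truths <- do.call(rbind, truth_rows)

  out_rep <- mahalanobis_outliers(subjects[, c("ADI_mono", "ADI_bino")],
                                  alpha = ec$alpha_outlier)
  keep <- !out_rep$flagged

  boot <- list(
    ADI_mono = bootstrap_ci(subjects$ADI_mono[keep], ec$n_boot, ec$ci_level,
                            seed = seed + 1L),
    ADI_bino = bootstrap_ci(subjects$ADI_bino[keep], ec$n_boot, ec$ci_level,
                            seed = seed + 2L),
    BSI_AE = bootstrap_ci(subjects$BSI_AE[keep], ec$n_boot, ec$ci_level,
                          seed = seed + 3L),
    BSI_FE = bootstrap_ci(subjects$BSI_FE[keep], ec$n_boot, ec$ci_level,
                          seed = seed + 4L)
  )

  phase_test <- paired_phase_test(deltas_72[keep], f_context = 7.2)
  corr <- adi_bsi_correlation(
    subjects$ADI_bino[keep] - subjects$ADI_mono[keep],
    subjects$BSI_AE[keep] - subjects$BSI_FE[keep])

  out <- list(subjects = subjects, truth = truths, outliers = out_rep,
              boot_ci = boot, phase_test = phase_test, correlation = corr,
              provenance = provenance(config, seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- subjects
    tab$config_hash <- out$provenance$config_hash
    tab$seed <- out$provenance$seed
    write_tsv(tab, file.path(out_dir, "indices.tsv"))
    write_tsv(as.data.frame(out_rep), file.path(out_dir, "outliers.tsv"))
    jsonlite::write_json(out$provenance, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}
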