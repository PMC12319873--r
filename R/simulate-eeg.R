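# Dichoptic SSVEP simulation: frequency-tagged sinusoidal components on a
# 15-electrode occipito-parietal montage with 1/f + white noise.

#' Occipito-parietal montage used by the surface Laplacian
#' @format list with `central` (6 electrodes) and `surround` (9 electrodes).
#' @export
SSVEP_MONTAGE <- list(
  central = c("O1", "Oz", "O2", "PO3", "POz", "PO4"),
  surround = c("P5", "P3", "P1", "Pz", "P2", "P4", "P6", "PO7", "PO8")
)

#' Enumerate the dichoptic stimulus conditions
#'
#' Full crossing of spatial frequency (low/high pass), ocularity (AE, FE,
#' binocular), and the two eye-to-tag-frequency assignments
#' (A: AE at 7.2 Hz & FE at 8 Hz; B: the reverse), in a stable order.
#'
#' @param f_tags the two tag frequencies in Hz (default 7.2 and 8).
#' @return data frame of 12 rows with `condition`, `sf`, `ocularity`,
#'   `assignment`, `f_AE`, `f_FE`.
#' @export
enumerate_conditions <- function(f_tags = c(7.2, 8)) {
  stopifnot(length(f_tags) == 2L, all(f_tags > 0))
  grid <- expand.grid(assignment = c("A", "B"),
                      ocularity = c("AE", "FE", "binocular"),
                      sf = c("low", "high"),
                      stringsAsFactors = FALSE)[, 3:1]
  grid$f_AE <- ifelse(grid$assignment == "A", f_tags[1], f_tags[2])
  grid$f_FE <- ifelse(grid$assignment == "A", f_tags[2], f_tags[1])
  grid$condition <- sprintf("%s_%s_%s", grid$sf, grid$ocularity, grid$assignment)
  grid[, c("condition", "sf", "ocularity", "assignment", "f_AE", "f_FE")]
}

#' Planted SSVEP ground truth
#'
#' First- and second-harmonic amplitudes per eye, the intermodulation
#' amplitude, planted response delays (converted to phase at each tag
#' frequency), per-eye binocular suppression, and the noise spectrum.
#' The AE amplitudes are derived from the FE amplitudes through the planted
#' monocular ADI.
#'
#' @param amp1_FE,amp2_FE fellow-eye first/second-harmonic amplitudes (uV).
#' @param adi planted monocular amplitude deficit: AE amplitudes are
#'   `FE * (1 - adi)`.
#' @param im_amp intermodulation amplitude at `f1 + f2` (uV), present only
#'   in binocular conditions.
#' @param bsi_AE,bsi_FE planted per-eye binocular suppression in (-1, 1].
#' @param delay_AE_ms,delay_FE_ms planted response delays (ms); a delayed
#'   response is `cos(2 pi f (t - delay))`.
#' @param f_tags the two tag frequencies (Hz).
#' @param noise_sd time-domain noise standard deviation (uV).
#' @param noise_exponent 1/f amplitude exponent of the noise spectrum.
#' @param noise_white_frac white-noise floor fraction of the spectral shape.
#' @param sf_gain named amplitude gains for the low/high spatial-frequency
#'   stimuli.
#' @return object of class `ssvep_truth`.
#' @export
ssvep_truth <- function(amp1_FE = 2, amp2_FE = 1, adi = 0.3, im_amp = 0.5,
                        bsi_AE = 0.4, bsi_FE = 0.05,
                        delay_AE_ms = 12.81, delay_FE_ms = 0,
                        f_tags = c(7.2, 8), noise_sd = 3,
                        noise_exponent = 1, noise_white_frac = 0.3,
                        sf_gain = c(low = 1, high = 1.2)) {
  amp1 <- c(AE = amp1_FE * (1 - adi), FE = amp1_FE)
  amp2 <- c(AE = amp2_FE * (1 - adi), FE = amp2_FE)
  if (any(c(amp1, amp2, im_amp) < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  bsi <- c(AE = bsi_AE, FE = bsi_FE)
  if (any(bsi <= -1 | bsi > 1)) stop("BSI values must lie in (-1, 1]", call. = FALSE)
  structure(
    list(amp1 = amp1, amp2 = amp2, im_amp = im_amp, bsi = bsi,
         delay_ms = c(AE = delay_AE_ms, FE = delay_FE_ms),
         f_tags = f_tags, adi = adi,
         noise_spec = list(sd = noise_sd, exponent = noise_exponent,
                           white_frac = noise_white_frac),
         sf_gain = sf_gain),
    class = "ssvep_truth"
  )
}

# 1/f + white shaped Gaussian noise, hermitian-symmetric spectral shaping
shaped_noise <- function(n, srate, sd_target, exponent, white_frac) {
  if (sd_target <= 0) return(numeric(n))
  f <- (seq_len(n) - 1) * srate / n
  f_fold <- pmin(f, srate - f)
  shape <- white_frac + (1 - white_frac) / pmax(f_fold, 0.5)^(exponent / 2)
  shape[1] <- 0
  x <- rnorm(n)
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y / sd(y) * sd_target
}

eye_components <- function(truth, eye, f, gain, t) {
  d <- truth$delay_ms[[eye]] / 1000
  gain * (truth$amp1[[eye]] * cos(2 * pi * f * (t - d)) +
          truth$amp2[[eye]] * cos(2 * pi * 2 * f * (t - d)))
}

#' Simulate a dichoptic SSVEP session
#'
#' Generates a continuous 15-channel recording covering the condition grid:
#' each trial carries the stimulated eye's tag components (first + second
#' harmonic) projected dominantly onto the central electrodes
#' (`central_gain` : `surround_gain`), monocular trials carry only that
#' eye's components, binocular trials carry both eyes' components scaled by
#' `1 - bsi` plus an intermodulation sinusoid at `f1 + f2`.  1/f + white
#' noise is added per channel over the whole recording.  Trials are
#' separated by `gap_s` of signal-free recording so filter transients never
#' reach the analysis windows.
#'
#' @param truth an `ssvep_truth`.
#' @param n_trials trials per condition.
#' @param srate sampling rate (Hz); must exceed 4x the highest harmonic.
#' @param trial_s trial duration in seconds (>= 6).
#' @param gap_s inter-trial gap in seconds.
#' @param seed integer seed (trial order and noise).
#' @param conditions condition table (default [enumerate_conditions()]).
#' @param central_gain,surround_gain signal projection gains for the two
#'   electrode groups.
#' @param analysis_window_s spectral analysis window length used for the
#'   on-grid check (default 5 s); a warning is recorded if a tag frequency
#'   does not fall on that window's frequency grid.
#' @return object of class `eeg_recording`: `data` (channels x samples,
#'   uV), `srate`, `channels`, `trials` (condition annotations with
#'   `onset_sample`), `trial_samples`; ground truth kept in the `truth`
#'   attribute.
#' @export
simulate_ssvep_recording <- function(truth, n_trials = 20, srate = 1000,
                                     trial_s = 6, gap_s = 2, seed = 1,
                                     conditions = enumerate_conditions(truth$f_tags),
                                     central_gain = 1, surround_gain = 0.2,
                                     analysis_window_s = 5) {
  max_harm <- 2 * max(truth$f_tags)
  if (srate < 4 * max_harm) stop("`srate` must be >= 4x the highest harmonic", call. = FALSE)
  if (trial_s < 6) stop("`trial_s` must be >= 6 s", call. = FALSE)
  offgrid <- truth$f_tags[abs(truth$f_tags * analysis_window_s -
                                round(truth$f_tags * analysis_window_s)) > 1e-9]
  if (length(offgrid)) {
    warning("tag frequency off the analysis grid: ",
            paste(offgrid, collapse = ", "), " Hz", call. = FALSE)
  }

  set.seed(as.integer(seed))
  order_idx <- unlist(lapply(seq_len(n_trials), function(b) sample(nrow(conditions))))
  trials <- conditions[order_idx, , drop = FALSE]
  rownames(trials) <- NULL

  ns_trial <- round(trial_s * srate)
  ns_gap <- round(gap_s * srate)
  n_tot <- nrow(trials)
  trials$onset_sample <- ns_gap + (seq_len(n_tot) - 1L) * (ns_trial + ns_gap) + 1L
  n_samples <- ns_gap + n_tot * (ns_trial + ns_gap)

  channels <- c(SSVEP_MONTAGE$central, SSVEP_MONTAGE$surround)
  proj <- c(rep(central_gain, length(SSVEP_MONTAGE$central)),
            rep(surround_gain, length(SSVEP_MONTAGE$surround)))

  t_loc <- (seq_len(ns_trial) - 1) / srate
  sig <- matrix(0, nrow = length(channels), ncol = n_samples)
  for (i in seq_len(n_tot)) {
    tr <- trials[i, ]
    gain <- truth$sf_gain[[tr$sf]]
    s <- numeric(ns_trial)
    if (tr$ocularity %in% c("AE", "binocular")) {
      g <- if (tr$ocularity == "binocular") gain * (1 - truth$bsi[["AE"]]) else gain
      s <- s + eye_components(truth, "AE", tr$f_AE, g, t_loc)
    }
    if (tr$ocularity %in% c("FE", "binocular")) {
      g <- if (tr$ocularity == "binocular") gain * (1 - truth$bsi[["FE"]]) else gain
      s <- s + eye_components(truth, "FE", tr$f_FE, g, t_loc)
    }
    if (tr$ocularity == "binocular" && truth$im_amp > 0) {
      f_im <- tr$f_AE + tr$f_FE
      d_im <- mean(truth$delay_ms) / 1000
      s <- s + gain * truth$im_amp * cos(2 * pi * f_im * (t_loc - d_im))
    }
    idx <- tr$onset_sample:(tr$onset_sample + ns_trial - 1L)
    sig[, idx] <- sig[, idx] + proj %o% s
  }

  nsp <- truth$noise_spec
  if (nsp$sd > 0) {
    for (ch in seq_along(channels)) {
      sig[ch, ] <- sig[ch, ] +
        shaped_noise(n_samples, srate, nsp$sd, nsp$exponent, nsp$white_frac)
    }
  }

  structure(
    list(data = sig, srate = srate, channels = channels, trials = trials,
         trial_samples = ns_trial),
    class = "eeg_recording",
    truth = truth,
    params = list(n_trials = n_trials, trial_s = trial_s, gap_s = gap_s,
                  seed = seed, central_gain = central_gain,
                  surround_gain = surround_gain)
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz, %d trials>\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$trials)))
  invisible(x)
}
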