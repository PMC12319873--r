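# SSVEP frequency-tagging analysis: filtering, Laplacian reference, trial
# averaging, amplitude spectra with harmonic summation, intermodulation, and
# least-squares phase.

fir_bandpass_coef <- function(lo, hi, srate, ntaps = NULL) {
  if (!(lo > 0 && hi > lo && hi < srate / 2)) {
    stop("invalid band: need 0 < lo < hi < srate/2", call. = FALSE)
  }
  if (is.null(ntaps)) {
    # Hamming transition width ~ 3.3 srate / N; keep the transition inside
    # (0, lo) on the low side and below Nyquist on the high side
    trans <- min(1.5, lo, srate / 2 - hi)
    ntaps <- ceiling(3.3 * srate / trans)
  }
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L # odd taps: integer group delay
  signal::fir1(ntaps - 1L, c(lo, hi) / (srate / 2), type = "pass")
}

apply_zero_phase <- function(b, x) {
  # linear-phase FIR: FFT convolution, then exact group-delay compensation
  gd <- (length(b) - 1L) %/% 2L
  y <- signal::fftfilt(b, c(x, numeric(length(b))))
  y[(gd + 1L):(gd + length(x))]
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass applied by FFT
#' convolution with exact group-delay compensation, giving zero phase shift
#' at all frequencies.  Passband gain is within 1% of unity and stopband
#' attenuation exceeds 40 dB beyond the transition band.
#'
#' @param x an `eeg_recording` (filtered per channel), an `eeg_series`, or a
#'   numeric vector (then `srate` is required).
#' @param lo,hi band edges in Hz, `0 < lo < hi < srate/2`.
#' @param srate sampling rate for a plain numeric input.
#' @param ntaps filter length (odd); defaults to a length giving a
#'   transition band of about `0.8 * min(lo, 2.5)` Hz.
#' @return same class as the input, filtered.
#' @export
bandpass <- function(x, lo, hi, srate = NULL, ntaps = NULL) {
  if (inherits(x, "eeg_recording")) {
    b <- fir_bandpass_coef(lo, hi, x$srate, ntaps)
    x$data <- t(apply(x$data, 1L, function(row) apply_zero_phase(b, row)))
    return(x)
  }
  if (inherits(x, "eeg_series")) {
    b <- fir_bandpass_coef(lo, hi, x$srate, ntaps)
    x$data <- apply_zero_phase(b, x$data)
    return(x)
  }
  if (is.null(srate)) stop("`srate` required for a numeric input", call. = FALSE)
  apply_zero_phase(fir_bandpass_coef(lo, hi, srate, ntaps), x)
}

#' Surface Laplacian reference
#'
#' Differential signal between the mean of the six central occipital
#' electrodes (O1, Oz, O2, PO3, POz, PO4) and the mean of the nine
#' parietal/parieto-occipital surround electrodes (P5, P3, P1, Pz, P2, P4,
#' P6, PO7, PO8).  Signals common to all electrodes cancel exactly.
#'
#' @param rec an `eeg_recording` containing all 15 montage channels.
#' @return an `eeg_series`: list with `data` (numeric), `srate`, `trials`,
#'   `trial_samples`.
#' @export
laplacian_reference <- function(rec) {
  needed <- c(SSVEP_MONTAGE$central, SSVEP_MONTAGE$surround)
  missing <- setdiff(needed, rec$channels)
  if (length(missing)) {
    stop("montage channel(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ci <- match(SSVEP_MONTAGE$central, rec$channels)
  si <- match(SSVEP_MONTAGE$surround, rec$channels)
  series <- colMeans(rec$data[ci, , drop = FALSE]) -
    colMeans(rec$data[si, , drop = FALSE])
  structure(list(data = series, srate = rec$srate, trials = rec$trials,
                 trial_samples = rec$trial_samples),
            class = "eeg_series")
}

#' @export
print.eeg_series <- function(x, ...) {
  cat(sprintf("<eeg_series: %d samples @ %g Hz, %d trials>\n",
              length(x$data), x$srate, nrow(x$trials)))
  invisible(x)
}

#' Average trials of one condition over an analysis window
#'
#' Point-wise mean across all trials of a condition, over a window given in
#' seconds relative to trial onset (`window = c(1, 6)` extracts the last
#' 5 s of a 6-s trial).  All trials are included; there is no artifact
#' rejection.
#'
#' @param x an `eeg_series` (e.g. from [laplacian_reference()]).
#' @param condition condition label matched against `x$trials$condition`.
#' @param window `c(start_s, end_s)` relative to trial onset.
#' @return numeric mean time series of `round((end - start) * srate)`
#'   samples, with `srate`, `window`, and `n_trials` attributes.
#' @export
average_trials <- function(x, condition, window = c(1, 6)) {
  tr <- x$trials[x$trials$condition == condition, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials of condition ", condition, call. = FALSE)
  s0 <- as.integer(round(window[1] * x$srate))
  s1 <- as.integer(round(window[2] * x$srate)) - 1L
  if (s1 - s0 + 1L > x$trial_samples) stop("window exceeds trial length", call. = FALSE)
  idx <- vapply(as.integer(tr$onset_sample), function(on) on + (s0:s1),
                integer(s1 - s0 + 1L))
  if (max(idx) > length(x$data)) stop("trial window outside the record", call. = FALSE)
  out <- rowMeans(matrix(x$data[idx], ncol = nrow(tr)))
  attributes(out) <- list(srate = x$srate, window = window, n_trials = nrow(tr))
  out
}

#' Single-sided amplitude spectrum
#'
#' FFT amplitude spectrum normalised so that a unit-amplitude sinusoid at an
#' exact frequency bin yields amplitude 1.0.  Resolution is
#' `srate / length(x)`; a 5-s window at 1000 Hz gives 0.2 Hz, placing 7.2,
#' 8, 14.4, 16, and 15.2 Hz on exact bins.
#'
#' @param x numeric time series.
#' @param srate sampling rate (Hz); taken from the `srate` attribute if
#'   absent.
#' @return object of class `amp_spectrum`: data frame with `freq`, `amp`,
#'   and attributes `resolution`, `srate`, `n`.
#' @export
amplitude_spectrum <- function(x, srate = attr(x, "srate")) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  a <- Mod(fft(as.numeric(x))) / n
  kmax <- floor(n / 2)
  amp <- a[1:(kmax + 1L)]
  dbl <- 2:(if (n %% 2L == 0L) kmax else kmax + 1L) # not DC, not Nyquist
  amp[dbl] <- 2 * amp[dbl]
  out <- data.frame(freq = (0:kmax) * srate / n, amp = amp)
  structure(out, class = c("amp_spectrum", "data.frame"),
            resolution = srate / n, srate = srate, n = n)
}

spectrum_value <- function(spec, f) {
  res <- attr(spec, "resolution")
  k <- f / res
  if (abs(k - round(k)) > 1e-6) {
    stop(sprintf("frequency %g Hz is off-grid (nearest bin offset %+.4g Hz)",
                 f, (k - round(k)) * res), call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k + 1L > nrow(spec)) stop("frequency beyond Nyquist", call. = FALSE)
  spec$amp[k + 1L]
}

#' Harmonic-summed tagged amplitude
#'
#' Amplitude at the tag frequency plus the amplitude at its second
#' harmonic, the per-condition SSVEP response measure.
#'
#' @param spec an `amp_spectrum`.
#' @param f_tag tag frequency (Hz); `f_tag` and `2 f_tag` must fall on the
#'   frequency grid.
#' @return summed amplitude (same units as the input signal).
#' @export
tagged_amplitude <- function(spec, f_tag) {
  spectrum_value(spec, f_tag) + spectrum_value(spec, 2 * f_tag)
}

#' Intermodulation amplitude
#'
#' Spectrum amplitude at `f1 + f2`, the lowest-order intermodulation
#' product of the two tag frequencies; a marker of nonlinear binocular
#' integration, producible only by combining the two eyes' inputs.
#'
#' @param spec an `amp_spectrum`.
#' @param f1,f2 the two tag frequencies (Hz); `f1 + f2` must be on-grid and
#'   below Nyquist.
#' @return amplitude at `f1 + f2`.
#' @export
im_amplitude <- function(spec, f1, f2) {
  f_im <- f1 + f2
  if (f_im >= attr(spec, "srate") / 2) stop("f1 + f2 is beyond Nyquist", call. = FALSE)
  spectrum_value(spec, f_im)
}

#' Noise floor around a frequency
#'
#' Mean amplitude of the `k` bins nearest to `f`, excluding bins within half
#' a resolution step of any frequency in `exclude` (signal bins).
#'
#' @param spec an `amp_spectrum`.
#' @param f centre frequency (Hz).
#' @param exclude frequencies whose bins must not enter the floor estimate.
#' @param k number of bins to average.
#' @return mean noise amplitude.
#' @export
spectrum_noise_floor <- function(spec, f, exclude = numeric(), k = 10) {
  res <- attr(spec, "resolution")
  ok <- spec$freq > 0
  for (fx in c(f, exclude)) ok <- ok & abs(spec$freq - fx) > res / 2
  idx <- which(ok)[order(abs(spec$freq[ok] - f))]
  mean(spec$amp[head(idx, k)])
}

#' ADI and BSI from tagged amplitudes
#'
#' Within-condition amblyopic deficit indices `ADI = (FE - AE)/FE` and the
#' per-eye binocular suppression indices
#' `BSI_eye = 1 - binocular_eye / monocular_eye`.
#'
#' @param mono_AE,mono_FE,bino_AE,bino_FE tagged amplitudes (uV) of each
#'   eye in the monocular and binocular conditions.
#' @param noise_floor optional noise amplitude; indices whose monocular
#'   amplitude does not exceed it are flagged unreliable.
#' @return list with `ADI_mono`, `ADI_bino`, `BSI_AE`, `BSI_FE`, and a
#'   logical `unreliable` flag per eye.
#' @export
indices_from_amplitudes <- function(mono_AE, mono_FE, bino_AE, bino_FE,
                                    noise_floor = NULL) {
  if (mono_AE <= 0 || mono_FE <= 0) {
    stop("monocular amplitudes must be positive", call. = FALSE)
  }
  unreliable <- c(AE = FALSE, FE = FALSE)
  if (!is.null(noise_floor)) {
    unreliable <- c(AE = mono_AE <= noise_floor, FE = mono_FE <= noise_floor)
  }
  list(ADI_mono = (mono_FE - mono_AE) / mono_FE,
       ADI_bino = (bino_FE - bino_AE) / bino_FE,
       BSI_AE = 1 - bino_AE / mono_AE,
       BSI_FE = 1 - bino_FE / mono_FE,
       unreliable = unreliable)
}

#' Least-squares phase at a single frequency
#'
#' Fits `a cos(2 pi f t) + b sin(2 pi f t)` to the series by least squares
#' and returns `phase = atan2(-b, a)`, so a pure cosine has phase 0 and a
#' pure sine has phase `-pi/2` (a delayed response has negative phase).
#'
#' @param x numeric time series (typically a band-passed condition mean over
#'   a window spanning integer cycle counts of `f`).
#' @param f analysis frequency (Hz).
#' @param srate sampling rate; taken from the `srate` attribute if absent.
#' @param t0 time of the first sample (s), so phases are referenced to
#'   stimulus onset regardless of window placement.
#' @return list with `phase` (radians in (-pi, pi]), `amplitude`, `a`, `b`,
#'   `f`.  A warning is issued when the window does not span an integer
#'   number of cycles.
#' @export
lsq_phase <- function(x, f, srate = attr(x, "srate"), t0 = 0) {
  n <- length(x)
  cycles <- n / srate * f
  if (abs(cycles - round(cycles)) > 1e-6) {
    warning(sprintf("window spans %.4f cycles of %g Hz (not an integer)",
                    cycles, f), call. = FALSE)
  }
  t <- t0 + (seq_len(n) - 1) / srate
  X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  ab <- unname(lm.fit(X, as.numeric(x))$coefficients)
  list(phase = atan2(-ab[2], ab[1]), amplitude = sqrt(sum(ab^2)),
       a = ab[1], b = ab[2], f = f)
}

#' Convert a phase difference to a delay in milliseconds
#'
#' `delay = wrap(phase_a - phase_b) / (2 pi f) * 1000`, wrapped to
#' `(-T/2, T/2]` of the period `T = 1000/f` ms.  Under the [lsq_phase()]
#' cosine convention a response delayed by `d` has phase `-2 pi f d`, so
#' the returned delay is positive when `b` occurs later than `a`.  A phase
#' difference of `2 pi - eps` wraps to a small negative delay, never to a
#' near-full period.
#'
#' @param phase_a,phase_b phases in radians at the same frequency.
#' @param f frequency in Hz (> 0).
#' @return delay of `b` relative to `a` in milliseconds, positive when `b`
#'   is later.
#' @export
phase_to_delay <- function(phase_a, phase_b, f) {
  if (any(f <= 0)) stop("`f` must be positive", call. = FALSE)
  wrap_pi(phase_a - phase_b) / (2 * pi * f) * 1000
}
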