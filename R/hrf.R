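# Canonical block haemodynamic response shared by the simulator and the GLM.
#
# The kernel is a gamma-difference impulse response convolved with the block
# boxcar on a fine time grid, then sampled at the TR.  The regressor for a
# sustained block is normalised to a plateau of 1 so that a fitted beta reads
# directly in percent signal change of the block plateau.  Using one kernel
# object on both sides keeps noiseless parameter recovery exact.

#' Gamma-difference haemodynamic impulse response
#'
#' A canonical double-gamma impulse response (peak ~5 s, undershoot ~15 s)
#' evaluated on a time grid.  Used internally by [block_regressor()]; exposed
#' for inspection and plotting.
#'
#' @param t time in seconds (vector, `t >= 0`).
#' @param peak,under gamma shape parameters for the positive lobe and the
#'   undershoot (seconds to mode).
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector, unit peak amplitude.
#' @export
hrf_gamma <- function(t, peak = 5, under = 15, ratio = 0.1) {
  stopifnot(all(t >= 0))
  g <- function(tt, m) (tt / m)^m * exp(m - tt) # mode at t = m, unit peak
  h <- g(t, peak) - ratio * g(t, under)
  h / max(h)
}

#' Block-design stimulus regressor
#'
#' Convolves the boxcar of one condition's blocks with the canonical impulse
#' response on a fine grid (`dt = 0.1` s) and samples the result at the TR.
#' The regressor is scaled so that a long block plateaus at 1.
#'
#' @param events event table as returned by [make_block_design()].
#' @param condition condition label to extract.
#' @param tr repetition time in seconds.
#' @param n_vols number of volumes in the run.
#' @return numeric vector of length `n_vols`.
#' @export
block_regressor <- function(events, condition, tr, n_vols) {
  stopifnot_scalar_pos(tr, "tr")
  ev <- events[events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events for condition ", condition, call. = FALSE)
  dt <- 0.1
  run_s <- n_vols * tr
  tfine <- seq(0, run_s, by = dt)
  box <- numeric(length(tfine))
  for (i in seq_len(nrow(ev))) {
    box[tfine >= ev$onset[i] & tfine < ev$onset[i] + ev$duration[i]] <- 1
  }
  h <- hrf_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tfine)] * dt
  # plateau normalisation: response of an infinitely long block
  conv <- conv / (sum(h) * dt)
  approx(tfine, conv, xout = (seq_len(n_vols) - 1) * tr, rule = 2)$y
}
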