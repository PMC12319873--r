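# Block design generation for the monocular/binocular fMRI experiment.

FMRI_CONDITIONS <- c("AE", "FE", "binocular")

#' Generate a pseudo-randomised, counterbalanced block design
#'
#' Builds a fixation-leading alternation `fix, stim, fix, ..., stim, fix` in
#' which each of the three stimulus conditions (amblyopic eye, fellow eye,
#' binocular) appears exactly `n_per_condition` times, in a pseudo-random
#' order drawn from the seed.  With the defaults (3 blocks per condition,
#' 18-s stimulus blocks, 12-s fixation blocks) a run comprises 9 stimulus and
#' 10 fixation blocks and lasts 282 s.
#'
#' @param n_per_condition number of blocks per stimulus condition (>= 1).
#' @param block_s stimulus block duration in seconds.
#' @param fix_s fixation block duration in seconds.
#' @param seed integer seed for the condition order.
#' @return a data frame with columns `onset`, `duration`, `condition`
#'   (levels `AE`, `FE`, `binocular`, `fixation`), blocks contiguous and
#'   non-overlapping.  Attribute `run_s` holds the total run duration.
#' @export
make_block_design <- function(n_per_condition = 3, block_s = 18, fix_s = 12,
                              seed = 1) {
  if (!is.numeric(n_per_condition) || n_per_condition < 1) {
    stop("`n_per_condition` must be >= 1", call. = FALSE)
  }
  stopifnot_scalar_pos(block_s, "block_s")
  stopifnot_scalar_pos(fix_s, "fix_s")
  n_per_condition <- as.integer(n_per_condition)

  order <- local({
    set.seed(as.integer(seed))
    sample(rep(FMRI_CONDITIONS, n_per_condition))
  })
  n_stim <- length(order)
  cond <- character(2L * n_stim + 1L)
  dur <- numeric(2L * n_stim + 1L)
  cond[seq(1L, 2L * n_stim + 1L, by = 2L)] <- "fixation"
  dur[seq(1L, 2L * n_stim + 1L, by = 2L)] <- fix_s
  cond[seq(2L, 2L * n_stim, by = 2L)] <- order
  dur[seq(2L, 2L * n_stim, by = 2L)] <- block_s

  out <- data.frame(
    onset = cumsum(c(0, dur[-length(dur)])),
    duration = dur,
    condition = cond,
    stringsAsFactors = FALSE
  )
  attr(out, "run_s") <- sum(dur)
  out
}

#' Total duration of an event table
#'
#' @param events event table from [make_block_design()].
#' @return run length in seconds.
#' @export
design_duration <- function(events) sum(events$duration)
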