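# Inverted encoding model for monocular channels.
#
# Forward model: each voxel's response is a linear mixture of two monocular
# channel responses, Y = W C.  W (voxel x 2, non-negative) is fit from the
# monocular conditions, where the channel design is known (identity for pure
# monocular stimulation).  Inverting the model on the binocular condition
# pools voxels and estimates the two channel responses C_bino by OLS; the
# per-eye binocular suppression index is 1 - C_bino.  The inversion undoes
# the partial-volume underestimation of suppression in ocular-biased voxels.

#' Fit non-negative monocular channel weights
#'
#' Per voxel, solves `W = argmin_{w >= 0} ||y - C_mono' w||^2` by
#' Lawson-Hanson non-negative least squares.  With the identity monocular
#' design this clamps negative monocular betas to zero, but the solver
#' handles arbitrary channel designs.
#'
#' @param y_mono voxels x conditions matrix of monocular betas (columns in
#'   the order of `C_mono`'s columns; default AE then FE).
#' @param c_mono channels x conditions design; default the 2 x 2 identity
#'   (`[1 0]'` for AE stimulation, `[0 1]'` for FE stimulation).
#' @return voxels x channels matrix `W`, non-negative.
#' @export
fit_weights_nnls <- function(y_mono, c_mono = diag(2)) {
  y_mono <- as.matrix(y_mono)
  if (ncol(y_mono) != ncol(c_mono)) {
    stop("monocular condition missing: need one beta column per design column",
         call. = FALSE)
  }
  A <- t(c_mono) # conditions x channels
  W <- t(apply(y_mono, 1L, function(y) pracma::lsqnonneg(A, y)$x))
  if (nrow(c_mono) == 1L) W <- matrix(W, ncol = 1L)
  colnames(W) <- rownames(c_mono) %||% c("AE", "FE")[seq_len(ncol(W))]
  W
}

#' Invert the channel model on binocular responses
#'
#' Estimates the channel response vector `C_bino` by unconstrained OLS
#' across the voxels of a depth bin / ROI:
#' `C_bino = argmin_C ||y_bino - W C||^2`.
#'
#' @param y_bino binocular betas, one per voxel.
#' @param w voxels x channels weight matrix from [fit_weights_nnls()].
#' @return named numeric channel responses, or all-`NA` with attribute
#'   `ill_posed = TRUE` when `rank(W) <` number of channels.
#' @export
invert_channels <- function(y_bino, w) {
  w <- as.matrix(w)
  if (length(y_bino) != nrow(w)) stop("voxel count mismatch", call. = FALSE)
  nch <- ncol(w)
  if (nrow(w) < nch || qr(w)$rank < nch) {
    out <- rep(NA_real_, nch)
    names(out) <- colnames(w)
    attr(out, "ill_posed") <- TRUE
    return(out)
  }
  cb <- lm.fit(w, y_bino)$coefficients
  names(cb) <- colnames(w)
  attr(cb, "ill_posed") <- FALSE
  cb
}

#' Binocular suppression index from channel responses
#'
#' `bsi = 1 - C_bino` per channel: the fraction of each eye's monocular
#' channel response suppressed under binocular viewing.  Ill-posed bins
#' propagate as `NA`.
#'
#' @param c_bino channel responses: a vector (one bin) or a bins x channels
#'   matrix / data frame.
#' @return same shape as the input, `1 - c_bino`.
#' @export
compute_bsi_fmri <- function(c_bino) {
  if (is.data.frame(c_bino)) c_bino <- as.matrix(c_bino)
  1 - c_bino
}

#' Depth-resolved IEM suppression profile
#'
#' Convenience wrapper running the full IEM per depth bin: channel weights
#' are fit per voxel from the monocular betas, the binocular betas of each
#' bin are inverted pooled across that bin's voxels, and the per-eye BSI is
#' `1 - C_bino`.
#'
#' @param glm a `glm_result` with `AE`, `FE`, `binocular` conditions.
#' @param depth per-voxel depths (numeric, `depth_volume`, or `NULL` for
#'   simulation truth), as in [laminar_profile()].
#' @param mask optional `vein_mask` or logical exclusion vector.
#' @param roi optional vertex set.
#' @param n_bins number of depth bins (default 3 layer compartments).
#' @return data frame with `bin`, `depth_lo`, `depth_hi`, `c_bino_AE`,
#'   `c_bino_FE`, `bsi_AE`, `bsi_FE`, `n_voxels`, `ill_posed`.
#' @export
iem_bsi_profile <- function(glm, depth = NULL, mask = NULL, roi = NULL,
                            n_bins = 3) {
  d <- resolve_depth(glm, depth)
  keep <- !is.na(d)
  if (!is.null(mask)) {
    excl <- if (inherits(mask, "vein_mask")) mask$voxel_excluded else as.logical(mask)
    keep <- keep & !excl
  }
  if (!is.null(roi)) keep <- keep & glm$vertex_id %in% roi
  if (!any(keep)) stop("no voxels remain after masking", call. = FALSE)

  beta <- glm$beta[keep, , drop = FALSE]
  d <- d[keep]
  W <- fit_weights_nnls(beta[, c("AE", "FE"), drop = FALSE])

  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, labels = FALSE,
             right = FALSE)
  bin[d >= 1] <- n_bins

  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (sum(sel) == 0L) {
      return(data.frame(bin = b, depth_lo = breaks[b], depth_hi = breaks[b + 1],
                        c_bino_AE = NA_real_, c_bino_FE = NA_real_,
                        bsi_AE = NA_real_, bsi_FE = NA_real_,
                        n_voxels = 0L, ill_posed = TRUE))
    }
    cb <- invert_channels(beta[sel, "binocular"], W[sel, , drop = FALSE])
    bsi <- compute_bsi_fmri(cb)
    data.frame(bin = b, depth_lo = breaks[b], depth_hi = breaks[b + 1],
               c_bino_AE = cb[["AE"]], c_bino_FE = cb[["FE"]],
               bsi_AE = bsi[["AE"]], bsi_FE = bsi[["FE"]],
               n_voxels = sum(sel),
               ill_posed = isTRUE(attr(cb, "ill_posed")))
  })
  do.call(rbind, rows)
}
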