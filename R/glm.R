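# Block-design general linear model.

legendre_drifts <- function(n_vols, order) {
  if (order < 1) return(NULL)
  x <- seq(-1, 1, length.out = n_vols)
  d <- vapply(seq_len(order), function(k) {
    p <- pracma::legendre(k, x)[1, ] # P_k(x)
    p
  }, numeric(n_vols))
  colnames(d) <- paste0("drift", seq_len(order))
  d
}

#' Fit a block-design GLM per voxel
#'
#' Ordinary least squares of each voxel's time series on the stimulus
#' regressors (block boxcars convolved with the canonical response,
#' [block_regressor()]), an intercept, Legendre polynomial drifts, and
#' optional motion nuisance columns.  Betas are rescaled to percent signal
#' change relative to the voxel's fitted baseline (the model intercept).
#'
#' @param bold a `bold_run`, or a voxels x volumes numeric matrix (then
#'   `events` and `tr` are required).
#' @param events event table; taken from the `bold_run` if omitted.
#' @param tr repetition time (s); taken from the `bold_run` if omitted.
#' @param drift_order number of Legendre drift polynomials (0 disables).
#' @param motion optional volumes x k matrix of motion regressors.
#' @param psc_baseline `"intercept"` (default) rescales betas by the fitted
#'   baseline; `"mean"` uses the voxel temporal mean.
#' @return object of class `glm_result`: `beta` (voxels x conditions, PSC),
#'   `residual_sd` (PSC), `mean_epi` (raw temporal mean), `baseline_hat`,
#'   `conditions`, plus voxel geometry (`vertex_id`, `depth_true`, `coords`,
#'   `grid`, `n_vertices`) when fitted on a `bold_run`.
#' @export
fit_block_glm <- function(bold, events = NULL, tr = NULL, drift_order = 3,
                          motion = NULL,
                          psc_baseline = c("intercept", "mean")) {
  psc_baseline <- match.arg(psc_baseline)
  geom <- NULL
  if (inherits(bold, "bold_run")) {
    events <- events %||% bold$events
    tr <- tr %||% bold$tr
    geom <- bold[c("vertex_id", "depth_true", "coords", "grid", "n_vertices")]
    data <- bold$data
  } else {
    data <- bold
    if (is.null(events) || is.null(tr)) {
      stop("`events` and `tr` are required for a plain data matrix", call. = FALSE)
    }
  }
  stopifnot_scalar_pos(tr, "tr")
  n_vols <- ncol(data)
  if (max(events$onset + events$duration) > n_vols * tr + 1e-9) {
    stop("events extend beyond the run", call. = FALSE)
  }

  found <- setdiff(unique(events$condition), "fixation")
  conditions <- c(intersect(FMRI_CONDITIONS, found),
                  setdiff(found, FMRI_CONDITIONS))
  Xs <- vapply(conditions, function(cnd) block_regressor(events, cnd, tr, n_vols),
               numeric(n_vols))
  X <- cbind(Xs, intercept = 1)
  if (drift_order > 0) X <- cbind(X, legendre_drifts(n_vols, drift_order))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- colnames(motion) %||% paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  fit <- lm.fit(X, t(data))
  B <- t(fit$coefficients) # voxels x p
  res <- t(fit$residuals)  # voxels x n_vols
  mean_epi <- rowMeans(data)
  base <- if (psc_baseline == "intercept") B[, "intercept"] else mean_epi
  div <- ifelse(base == 0, 1, base) # all-zero voxels: keep betas at 0, not NaN
  beta_psc <- 100 * B[, conditions, drop = FALSE] / div
  dfres <- n_vols - ncol(X)
  resid_sd <- 100 * sqrt(rowSums(res^2) / max(dfres, 1L)) / div

  out <- c(list(beta = beta_psc, residual_sd = resid_sd, mean_epi = mean_epi,
                baseline_hat = base, conditions = conditions,
                design = X, events = events, tr = tr),
           geom %||% list())
  structure(out, class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result: %d voxels, conditions: %s>\n",
              nrow(x$beta), paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Average GLM results across runs
#'
#' Element-wise average of betas, residual SDs, and mean EPI over runs fit
#' on the same voxel grid.
#'
#' @param glms list of `glm_result` objects.
#' @return a `glm_result` with averaged maps.
#' @export
average_glm <- function(glms) {
  stopifnot(length(glms) >= 1L)
  out <- glms[[1L]]
  if (length(glms) > 1L) {
    out$beta <- Reduce(`+`, lapply(glms, `[[`, "beta")) / length(glms)
    out$residual_sd <- Reduce(`+`, lapply(glms, `[[`, "residual_sd")) / length(glms)
    out$mean_epi <- Reduce(`+`, lapply(glms, `[[`, "mean_epi")) / length(glms)
  }
  out
}
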