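# Laminar profiles, vein exclusion, ADI, and ocular-bias ROI selection.

#' Map voxel values onto the surface
#'
#' Vertex value = mean over the voxels of that vertex's cortical column.
#'
#' @param values numeric per voxel.
#' @param vertex_id assigned vertex per voxel.
#' @param n_vertices total vertex count.
#' @return numeric vector of length `n_vertices`, `NA` where no voxel maps.
#' @export
map_voxels_to_surface <- function(values, vertex_id, n_vertices) {
  out <- rep(NA_real_, n_vertices)
  m <- tapply(values, vertex_id, mean)
  out[as.integer(names(m))] <- m
  out
}

#' Identify vein-contaminated cortical columns
#'
#' Maps the mean EPI intensity and the across-condition mean BOLD response
#' onto the surface and flags a vertex as a large vein if its intensity
#' falls below `intensity_frac` of the across-vertex average intensity, or
#' its mean response exceeds `psc_max` percent signal change.  Flags remove
#' entire columns: every voxel of a flagged vertex is excluded across all
#' cortical depths.
#'
#' @param glm a `glm_result` fitted on a `bold_run` (carries the voxel-to-
#'   vertex assignment).
#' @param intensity_frac intensity threshold as a fraction of the average
#'   vertex intensity (default 0.70).
#' @param psc_max BOLD response ceiling in percent signal change (default 10).
#' @return object of class `vein_mask`: `vertex_flag` (logical per vertex),
#'   `voxel_excluded` (logical per voxel), and the surface maps used.
#' @export
vein_mask <- function(glm, intensity_frac = 0.7, psc_max = 10) {
  if (is.null(glm$vertex_id)) {
    stop("`glm` carries no voxel-to-vertex assignment", call. = FALSE)
  }
  nv <- glm$n_vertices
  epi_surf <- map_voxels_to_surface(glm$mean_epi, glm$vertex_id, nv)
  resp_surf <- map_voxels_to_surface(rowMeans(glm$beta), glm$vertex_id, nv)
  avg_int <- mean(epi_surf, na.rm = TRUE)
  flag <- !is.na(epi_surf) &
    (epi_surf < intensity_frac * avg_int | resp_surf > psc_max)
  if (all(flag[!is.na(epi_surf)])) {
    stop("vein rule excluded every vertex (avg intensity ",
         format(avg_int), "); check thresholds", call. = FALSE)
  }
  structure(
    list(vertex_flag = flag, voxel_excluded = flag[glm$vertex_id],
         epi_surface = epi_surf, response_surface = resp_surf,
         intensity_frac = intensity_frac, psc_max = psc_max),
    class = "vein_mask"
  )
}

resolve_depth <- function(glm, depth) {
  if (is.null(depth)) return(glm$depth_true)
  if (inherits(depth, "depth_volume")) {
    if (is.null(glm$grid) || is.null(depth$grid)) {
      stop("grid metadata needed to match a depth_volume to the GLM voxels",
           call. = FALSE)
    }
    d <- rep(NA_real_, nrow(glm$beta))
    m <- match(glm$grid$index, depth$grid$index)
    d[!is.na(m)] <- depth$depth[m[!is.na(m)]]
    return(d)
  }
  as.numeric(depth)
}

#' Depth-resolved condition profiles
#'
#' Averages per-condition betas across the voxels of each depth bin,
#' after vein-column exclusion and optional restriction to an ROI vertex
#' set.  With `n_bins = 3` the bins are the equal-volume layer compartments.
#'
#' @param glm a `glm_result`.
#' @param depth per-voxel depths: numeric vector, a `depth_volume` sharing
#'   the GLM's grid, or `NULL` to use the simulation ground-truth depths.
#' @param mask optional `vein_mask` (or logical per-voxel exclusion vector).
#' @param roi optional integer vertex set restricting the profile.
#' @param n_bins number of equal-width equivolume depth bins.
#' @return data frame with `bin`, `depth_lo`, `depth_hi`, `condition`,
#'   `mean_beta` (`NA` for empty bins), `n_voxels`.
#' @export
laminar_profile <- function(glm, depth = NULL, mask = NULL, roi = NULL,
                            n_bins = 3) {
  d <- resolve_depth(glm, depth)
  keep <- !is.na(d)
  if (!is.null(mask)) {
    excl <- if (inherits(mask, "vein_mask")) mask$voxel_excluded else as.logical(mask)
    keep <- keep & !excl
  }
  if (!is.null(roi)) {
    if (is.null(glm$vertex_id)) stop("ROI given but no vertex assignment", call. = FALSE)
    keep <- keep & glm$vertex_id %in% roi
  }
  if (!any(keep)) stop("no voxels remain after masking", call. = FALSE)

  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(d[keep], breaks = breaks, include.lowest = TRUE,
             labels = FALSE, right = FALSE)
  bin[d[keep] >= 1] <- n_bins
  beta <- glm$beta[keep, , drop = FALSE]

  rows <- expand.grid(bin = seq_len(n_bins), condition = glm$conditions,
                      stringsAsFactors = FALSE)
  rows$depth_lo <- breaks[rows$bin]
  rows$depth_hi <- breaks[rows$bin + 1]
  rows$mean_beta <- mapply(function(b, cnd) {
    v <- beta[bin == b, cnd]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, rows$bin, rows$condition)
  rows$n_voxels <- vapply(rows$bin, function(b) sum(bin == b), integer(1))
  rows[, c("bin", "depth_lo", "depth_hi", "condition", "mean_beta", "n_voxels")]
}

#' Amblyopic deficit index
#'
#' `adi = (FE - AE) / FE`: the proportional response loss of the amblyopic
#' eye relative to the fellow eye.  Positive values mean AE loss; bins with
#' non-positive FE response are flagged undefined (`NA`).
#'
#' @param ae,fe response amplitudes (matched vectors, e.g. per depth bin).
#' @return numeric vector of ADI values with `NA` where `fe <= 0`.
#' @export
compute_adi <- function(ae, fe) {
  if (length(ae) != length(fe)) stop("AE and FE bins must match", call. = FALSE)
  ifelse(fe > 0, (fe - ae) / fe, NA_real_)
}

#' ADI depth profile from a condition profile table
#'
#' @param profile output of [laminar_profile()] containing `AE` and `FE`
#'   conditions.
#' @return data frame with `bin`, `depth_lo`, `depth_hi`, `adi`, `n_voxels`.
#' @export
adi_profile <- function(profile) {
  ae <- profile[profile$condition == "AE", ]
  fe <- profile[profile$condition == "FE", ]
  stopifnot(identical(ae$bin, fe$bin))
  data.frame(bin = ae$bin, depth_lo = ae$depth_lo, depth_hi = ae$depth_hi,
             adi = compute_adi(ae$mean_beta, fe$mean_beta),
             n_voxels = ae$n_voxels)
}

#' Select ocular-biased vertex sets
#'
#' Ranks vertices by the AE-FE beta difference and returns the top `frac`
#' (AE-biased) and bottom `frac` (FE-biased) of the distribution, ties
#' broken by stable vertex index order.
#'
#' @param beta_ae,beta_fe surface beta maps (per vertex; `NA` vertices are
#'   ignored).
#' @param frac fraction per side, in (0, 0.5).
#' @return list with integer vertex vectors `AE_biased` and `FE_biased`.
#' @export
select_ocular_rois <- function(beta_ae, beta_fe, frac = 0.1) {
  if (frac <= 0 || frac >= 0.5) stop("`frac` must be in (0, 0.5)", call. = FALSE)
  diffmap <- beta_ae - beta_fe
  ok <- which(!is.na(diffmap))
  k <- floor(frac * length(ok) + 1e-9)
  if (k < 1) stop("`frac` selects no vertices", call. = FALSE)
  ord <- ok[order(diffmap[ok], ok, decreasing = c(TRUE, FALSE), method = "radix")]
  list(AE_biased = sort(head(ord, k)),
       FE_biased = sort(head(rev(ord), k)))
}

#' Split-half cross-validated ROI profiles
#'
#' Odd runs define the ocular-biased vertex sets used to extract profiles
#' from the even runs, and vice versa; the two extractions are averaged.
#' This removes the selection bias that arises when the same noisy data both
#' select and quantify the ROI.
#'
#' @param glms list of per-run `glm_result` objects (>= 2 runs) on the same
#'   voxel grid.
#' @param depth per-voxel depths (numeric or `depth_volume`), as in
#'   [laminar_profile()].
#' @param mask optional `vein_mask` applied to all runs.
#' @param frac ROI fraction per side.
#' @param n_bins depth bins.
#' @return list with `AE_biased` and `FE_biased` averaged profile tables.
#' @export
split_half_rois <- function(glms, depth = NULL, mask = NULL, frac = 0.1,
                            n_bins = 3) {
  if (length(glms) < 2L) stop("split-half needs >= 2 runs", call. = FALSE)
  odd <- average_glm(glms[seq_along(glms) %% 2L == 1L])
  even <- average_glm(glms[seq_along(glms) %% 2L == 0L])

  half_profiles <- function(localizer, held_out) {
    nv <- localizer$n_vertices
    ae_s <- map_voxels_to_surface(localizer$beta[, "AE"], localizer$vertex_id, nv)
    fe_s <- map_voxels_to_surface(localizer$beta[, "FE"], localizer$vertex_id, nv)
    rois <- select_ocular_rois(ae_s, fe_s, frac)
    lapply(rois, function(r) {
      laminar_profile(held_out, depth = depth, mask = mask, roi = r,
                      n_bins = n_bins)
    })
  }
  p1 <- half_profiles(odd, even)
  p2 <- half_profiles(even, odd)
  avg <- function(a, b) {
    out <- a
    out$mean_beta <- (a$mean_beta + b$mean_beta) / 2
    out$n_voxels <- as.integer(round((a$n_voxels + b$n_voxels) / 2))
    out
  }
  list(AE_biased = avg(p1$AE_biased, p2$AE_biased),
       FE_biased = avg(p1$FE_biased, p2$FE_biased))
}
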